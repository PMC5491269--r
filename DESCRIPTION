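Package: dermalign
Title: Quantitative Dermal Collagen Architecture, Fibrosis Signatures and
    Fibroblast Migration Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies dermal fibrosis from histology-like images and links
    it to transcriptomic and cell-motility readouts. Segments collagen
    bundles from stained sections, measures epidermis-relative bundle angles,
    and scores bundle alignment by two-component axial von Mises mixture
    decomposition (the alignment score is the weight of the dominant angular
    peak). Computes dermis thickness (area over epidermal contour length) and
    total collagen fraction. Identifies per-metric gene signatures by
    intersecting differentially expressed genes with genes whose expression
    correlates with each histology metric. Summarises time-lapse fibroblast
    trajectories (net displacement, accumulated distance, directionality) and
    tests substrate and knockdown effects. Ships seeded synthetic-data
    generators (stained slides with ground-truth bundle tables, negative
    binomial count matrices with planted metric-correlated genes, persistent
    random-walk trajectories) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
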