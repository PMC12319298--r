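Package: xylemtaper
Title: Root-to-Leaf Scaling of Xylem Conduit Dimensions and Collapse Safety
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing tip-to-base widening of xylem conduits and the
    structural safety of their walls. Provides conduit-level anatomy metrics
    (thickness-to-span ratio, Mork's index, hydraulic diameter), standardized
    major axis and ordinary least squares scaling fits in log-log space with
    slope, elevation and curvature tests and AIC model comparison, a
    bin-balanced subsampling and bootstrap procedure that corrects the severe
    sampling imbalance of quantitative wood-anatomy datasets, a numerical
    soil-plant-atmosphere model of the critical thickness-to-span ratio at
    which conduit walls collapse under sap tension, and a synthetic conduit
    table generator with known scaling exponents for validating the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
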