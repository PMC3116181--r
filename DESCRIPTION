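Package: aapls
Title: Composition-Activity PLS Modeling of Antioxidant Protein Hydrolysates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative structure-activity (QSAR) modeling of food protein
    hydrolysates from bulk amino-acid composition. Builds descriptor
    matrices from percent amino-acid composition (individual residues,
    physicochemical group sums, and composition-weighted Hellberg 3-z scale
    sums), fits single-response partial least squares regressions by the
    NIPALS algorithm on autoscaled data, selects significant latent
    components by cross-validated Q2, tests model validity by response
    permutation with intercept limits, and classifies strong and weak
    contributor variables from VIP scores and coefficient signs. Includes a
    bundled 16-sample hydrolysate composition panel and a synthetic-data
    generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
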