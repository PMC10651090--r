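Package: melanotherm
Title: Melanistic Pattern Extraction and Thermoregulation Analysis from
    Repeat Photography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments stable melanistic coloration from repeated visible-light
    photographs of the same freely moving animal and analyses its role in
    thermoregulation. Images are normalized in Hue-Lightness-Saturation space
    against an in-frame grayscale reference, foreground pixels are clustered in
    RGB space with k-means++-initialized (bisecting) k-means, and per-image
    melanistic proportion and class-wise luminance are tracked over time.
    Downstream tools compute eye-averaged body temperature from per-body-part
    infrared readings, per-block summaries, heating and cooling rates, and the
    block-based statistical battery (correlations, normality-gated paired
    contrasts, linear models with interactions and Cook's-distance influence
    diagnostics). A synthetic-data module generates spotted-animal image series
    and thermal cohorts with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    mgcv,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    EBImage,
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
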