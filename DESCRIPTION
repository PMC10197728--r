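Package: cassir
Title: Coded Aperture Snapshot Spectral Imaging: Simulation,
    Reconstruction and Resolution Metrology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for coded aperture snapshot spectral imaging (CASSI):
    a physically faithful forward simulator (binary coded mask, prism
    dispersion, sensor integration) expressed as a matrix-free linear
    operator with exact adjoint and diagonal Gram; an augmented-Lagrangian
    ADMM reconstructor with a one-shot closed-form data projection and a
    pluggable denoiser (anisotropic total variation by default); prism
    dispersion calibration utilities and USAF-1951 resolution metrology;
    and synthetic phantoms (rainbow-letter, USAF target, eye vasculature)
    so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    ggplot2,
    jsonlite,
    png,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
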