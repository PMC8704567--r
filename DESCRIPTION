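Package: mothwind
Title: Backward-Trajectory Source Inference for Wind-Borne Moth Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the source regions of wind-borne insect
    migration events, built around the first detections of fall armyworm
    (Spodoptera frugiperda) in northern Australia. Provides a gridded
    meteorological field container with quadrilinear space-time interpolation,
    nocturnal flight-behaviour rules (downwind flight with a fixed self-powered
    airspeed, dusk take-off, dawn landing over land, over-sea extension, and a
    low-temperature flight gate), a forward/backward trajectory integrator with
    stepping-stone multi-leg reconstruction, endpoint-validity filtering and
    source-region summaries, nocturnal wind-rose climatology and
    vertical-velocity (omega) downdraft diagnostics, and synthetic monsoon
    weather scenarios with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    grDevices,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    ncdf4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
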