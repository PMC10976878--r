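Package: rxsmoke
Title: Comparing the Smoke and Health Impacts of Wildfires and Prescribed Burns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A scenario pipeline for comparing fine-particle (PM2.5) air-quality
    and short-term health impacts of fires burning under wildfire conditions
    versus prescribed-burn conditions. Builds fire emission inventories from
    burned area, fuel consumption and land-cover emission factors; re-schedules
    fires onto meteorologically suitable prescribed-burn days in spring and
    fall, optionally avoiding forecast high-exposure days; disperses smoke with
    a transparent advection-diffusion-decay surrogate kernel; and computes
    population-weighted PM2.5 exposure and excess short-term mortality from a
    relative-risk function, with normalized mean bias/error factor statistics
    for model evaluation. Ships seeded synthetic generators for meteorology,
    fire events, fuel beds and population so the full pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
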