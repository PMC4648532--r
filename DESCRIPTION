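Package: murrelog
Title: Geolocation-Immersion-Pressure Logger Analysis for Diving Seabirds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Processing chain for combined geolocation-immersion-pressure
    loggers deployed on diving seabirds such as Common Murres (Uria aalge).
    Converts raw logger channels into daily positions (threshold light-level
    geolocation with sun-angle bias correction and track filtering), activity
    states and colony-attendance phenology from temperature-gated wet/dry
    records, dive and dive-bout metrics (maximum-likelihood bout-ending
    criterion from a two-process exponential mixture of post-dive intervals),
    an index of prey-patch quality, parental-care life-history stages with
    offspring-independence estimation, kernel utilization distributions with
    core-area overlap, and diet-tissue fractionation adjustment of stable
    isotope values. Includes a seeded synthetic deployment generator with
    full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
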