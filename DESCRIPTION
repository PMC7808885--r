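Package: sociobadge
Title: Contact Network Analysis of Hospital Staff from Wearable Sociometric Badges
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for turning raw wearable sociometric-badge event streams
    (dyadic infrared detections, body-motion frequency samples, and location
    beacon pings) into active face-to-face interactions, spatiotemporal zone
    occupancy maps, profession-pair contact heatmaps, threshold-layered
    sociograms, node centrality measures, and core/periphery structure fits,
    modelled on intensive-care-unit interprofessional communication studies.
    Includes a seeded synthetic badge-stream generator emulating a 76-member,
    nine-profession ICU staff on a three-shift rotation with handover bursts,
    so the full pipeline is testable without access to any sensor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
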