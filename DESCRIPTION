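Package: spotqa
Title: Log-File Based Patient QA for Pencil-Beam Scanning Proton Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Patient-specific quality assurance for pencil-beam scanning
    (spot scanning) proton therapy from machine delivery log files.
    Compares delivered spot monitor units, lateral positions and sizes
    against the treatment plan, decomposes positional deviations of each
    energy layer into a systematic (layer shift) and a random (per-spot
    scatter) component, flags tolerance violations, aggregates fleet-level
    trends across rooms and sessions, reconstructs the delivered plan from
    the log and compares planned versus delivered planar dose by Gaussian
    spot superposition and gamma analysis. Includes readers and writers
    for a documented CSV log dialect and DICOM RT Ion Plans, and a
    synthetic delivery simulator with known ground truth so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
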