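Package: diaqc
Title: Acquisition Quality Control and Isolation-Window Optimization for DIA Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring and optimizing data-independent acquisition
    (DIA) and multiplexed plexDIA proteomics experiments. Extracts per-scan
    acquisition metrics (injection times, total ion current, isolation
    windows) from mzML files, parses DIA-NN-style search reports with
    channel-aware annotation for mTRAQ 3-plex sets, computes quality-control
    metrics (data completeness, quantification variability, identification
    counts, FDR curves, ion maps), places MS2 isolation windows by equal m/z,
    equal ion current, or equal precursor count, models Orbitrap duty-cycle
    timing and elution-apex sampling, and ships a synthetic multi-channel
    LC-MS run simulator so the whole pipeline is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mzR,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
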