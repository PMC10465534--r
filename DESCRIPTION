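Package: starkit
Title: Kinetic Modeling and Plate-Reader Analysis of Regulatory RNA Arrays
Version: 0.1.0
Authors@R: person("starkit", "developers", role = c("aut", "cre"),
    email = "starkit@example.org")
Description: Tools for designing and analysing tandem arrays of small
    transcription activating RNAs (STARs). Provides a kinetic model of a
    regulatory RNA array transcription unit (array transcription, Csy4
    cleavage releasing STAR copies, STAR-dependent anti-termination of a
    target RNA), composition of transcription units into amplifier, cascade
    and multiplex circuits, the standard plate-reader fluorescence
    normalisation pipeline (blank correction, FL/OD, autofluorescence
    subtraction, fold activation, standard curves, copy-number correlation,
    hypothesis tests), a synthetic plate-reader data generator with
    parameter recovery, and an in-silico Golden-Gate-style assembler for
    RNA array sequences.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
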