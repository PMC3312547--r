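Package: oesoEIT
Title: Simulation Study of an Oesophageal Internal Electrode for Cardiac
    Electrical Impedance Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: In-silico comparison of an internal (oesophageal) electrode
    against an all-external 16-electrode ring for cardiac-region electrical
    impedance tomography (EIT). Provides a deterministic graded tetrahedral
    mesher for cylindrical thorax phantoms with lung and blood-target
    inclusions, a complete-electrode-model finite-element forward solver with
    adjacent-pair stimulation, linearized Tikhonov difference reconstruction
    with automatic L-curve corner selection of the regularization parameter,
    GREIT-style figures of merit (amplitude response, position error,
    resolution, shape deformation, ringing), and pipeline drivers that run the
    position-sweep and electrode-arrangement comparison experiments end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
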