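Package: cedplan
Title: Connectivity-Guided Planning of Convection-Enhanced Drug Delivery to the Putamen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulation-based planning of convection-enhanced drug
    delivery (CED) into the putamen. Provides AC-PC based quadrant
    parcellation of the putamen, deterministic single-tensor streamline
    tractography with connection-presence counting across a cohort,
    straight-trajectory safety classification against critical-structure
    distance maps, a genetic-algorithm optimizer for stepwise spherical
    infusion plans along a trajectory, and the paired statistics (mid-p
    McNemar, paired t) used to compare frontal and occipital approaches.
    Includes a fully ground-truthed synthetic diffusion phantom generator so
    the whole pipeline can be exercised end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
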