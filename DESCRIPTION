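Package: hrpfsasa
Title: Absolute Side-Chain Solvent Accessibility from Hydroxyl Radical
    Protein Footprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts multi-point hydroxyl radical protein footprinting
    (FPOP HR-HRPF) measurements into absolute per-residue side-chain
    solvent accessible surface area (SASA). Provides a deterministic
    Shrake-Rupley SASA engine with Gly-X-Gly fully-exposed reference
    values, residue-level oxidation quantification from ETD fragment
    ions, per-residue dose-response regression against adenine radical
    dosimetry, protection-factor normalization by intrinsic amino-acid
    reactivity, native:denatured ratio normalization that cancels
    sequence-context effects, empirical linear calibration of normalized
    reactivity to fractional SASA with leave-one-out jackknife
    validation, and SASA-RMSD scoring for ranking candidate structural
    models against experimentally derived surface accessibility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
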