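Package: abepitope
Title: Structure Descriptors for Epitope Prediction on Therapeutic Antibodies
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Identifies the epitope regions that anti-drug antibodies (ADA)
    recognize on immunogenic therapeutic antibodies (iAb). From an iAb-ADA
    complex in PDB format the package labels epitope residues by a 5 Angstrom
    nearest-heavy-atom contact rule, partitions the antibody into core,
    surface non-immunogenic and epitope residues, and builds a 151-element
    per-residue structure descriptor from disulfide-anchored distances,
    radial-shell AAindex micro-environment summaries and layered accessible
    surface area (computed with a built-in Shrake-Rupley implementation).
    A ridge-penalised logistic regression classifies surface residues as
    epitope versus non-immunogenic with ten-fold cross-validation, and
    region-level analyses (amino-acid composition, AAindex t-tests,
    Kabat-CDR epitope classification, substitution/insertion census against
    background antibodies) are provided, together with a deterministic
    synthetic-structure generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    bio3d,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    optparse,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
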