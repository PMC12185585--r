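Package: ldhquant
Title: Geometric Quantification and Grading of Lumbar Disc Herniation on Axial MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies lumbar disc herniation (LDH) on axial T2 lumbar MRI
    slices from a disc segmentation and nine anatomical keypoints. Partitions
    the spinal canal into the Wiltse mediolateral zones (central canal,
    subarticular, foraminal and extraforaminal, left and right) from the
    inter-facet line, measures the signed protrusion distance of the disc
    beyond that line in millimetres and the anteroposterior sagittal diameter
    index, and assigns a four-level severity grade and an eight-label region,
    combined into an 18-category classification. Reads and writes LabelMe
    JSON, YOLO segmentation and pose label text, PNG and single-frame DICOM;
    orchestrates a dual-branch detection workflow with pluggable detector
    stages; evaluates predictions with mask IoU, keypoint mean error in mm,
    multiclass accuracy, precision and F1, and Cohen's kappa with asymptotic
    confidence intervals and agreement bands; and generates parameterized
    axial-slice phantoms with known ground truth so the whole toolchain is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    yaml,
    EBImage,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
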