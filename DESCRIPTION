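Package: neodose
Title: RF Dosimetry and Thermal Safety Modelling for Neonatal Ultra-High-Field MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-based radiofrequency dosimetry and bioheat modelling for
    safety assessment of neonatal imaging in a 7 Tesla adult head coil.
    Provides synthetic neonate voxel phantoms, age-adjusted tissue dielectric
    properties, pointwise / region-averaged / 10 g mass-averaged specific
    absorption rate (SAR) with the usual normalizations (input power, net
    forward power, absorbed power, mean squared transmit field B1+ in a
    central axial slice), an explicit finite-difference Pennes bioheat solver
    with convective surface losses, an insulating blanket layer and a
    variable blood-pool core temperature, and IEC-style compliance evaluation
    including drive-power computation, limit-crossing detection and
    heat-transfer-coefficient sensitivity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
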