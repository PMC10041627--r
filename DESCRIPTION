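Package: elastmap
Title: Anisotropic Deformability Maps from Elastic Stiffness Tensors of Molecular Crystals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns 6x6 Voigt stiffness matrices of molecular crystals into
    anisotropic deformability maps. Provides Voigt-notation tensor algebra
    (stiffness/compliance inversion, fourth-order conversion, rotation, Born
    stability, Voigt averages), directional Young's and shear modulus surfaces
    with global extrema and anisotropy indices, crystallographic-plane slices,
    elastic-constant extraction from stress-strain series with a synthetic
    stress engine, periodic hydrogen-bond/close-contact detection in crystal
    structures, and quantitative alignment of modulus maxima with contact
    networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
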