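Package: taamsf
Title: Aspherical and Independent-Atom Scattering Factors for Crystal Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes atomic scattering factors and crystallographic structure
    factors for the independent atom model (IAM) and the transferable
    aspherical atom model (TAAM, Hansen-Coppens multipolar formalism).
    Includes a documented text schema for multipolar parameter banks,
    chemistry-aware atom typing with a three-level fallback hierarchy
    (multipolar, spherical Slater, Gaussian IAM), closed-form Fourier-Bessel
    transforms of Slater-type radial functions, direct-summation structure
    factors with analytic gradients with respect to atomic parameters,
    X-ray to electron scattering conversion via the Mott-Bethe formula, and
    Fourier synthesis of electron-density, electrostatic-potential and
    TAAM-minus-IAM deformation maps written as CCP4/MRC files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
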