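Package: tubepinn
Title: Multi-Case Physics-Informed Neural Networks for 2D Stenotic Tube Flows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Physics-informed neural network (PINN) surrogates for steady
    incompressible flow in a family of 2D channels with a Gaussian narrowing,
    parameterized by narrowing amplitude and length scale. Implements three
    multi-case architectures (mixed network, hypernetwork, DeepONet-style modes
    network) over a SiLU fully connected backbone, tube-specific coordinate
    inputs, unit-normalized Navier-Stokes and boundary-condition losses, a
    gradient-enhanced (gPINN) case-derivative loss, Adam training with
    collocation pools, analytic straight-channel references, wall shear stress,
    and relative L2 error reporting. Exact first- to third-order derivatives of
    the network outputs with respect to coordinates and case parameters are
    computed with an in-package truncated-Taylor forward mode paired with a
    reverse pass for parameter gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
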