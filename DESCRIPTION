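Package: hemiscan
Title: Neurodynamic Simulation of Visual Search and Line Bisection in
    Hemianopia and Hemineglect
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A biased-competition neurodynamic model of visual attention and
    eye movements, with simulated cortical lesions. The model couples a
    retina/V1 front end (orientation- and colour-selective maps at two
    spatial scales, endstopped line-termination detectors), a ventral stream
    (V4-like extrastriate feature maps with optional collinear lateral
    connectivity, and object competition in IT under a frontal search bias)
    and a dorsal stream (a retinotopic parietal priority map integrating
    stimulus drive, scene-based novelty, spatial-compensation and
    bisection-task biases). Unilateral step or gradient lesions of the V1 or
    parietal module reproduce hemianopic and hemineglect scanpaths during
    conjunction search and line bisection, including the contralesional
    bisection error of chronic hemianopia and the large ipsilesional error of
    hemineglect, and two cortical compensation mechanisms: a contralesional
    spatial attention bias and strengthened extrastriate lateral connections
    supporting form completion into the blind field.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
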