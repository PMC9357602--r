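Package: turingdelay
Title: Turing Pattern Formation Under Fixed and Distributed Gene Expression
    Delays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Linear stability analysis and numerical simulation of
    two-species reaction-diffusion systems whose gene-expression steps carry
    a fixed or continuously distributed time delay. Implements truncated
    symmetric and skewed Gaussian delay kernels and their Laplace-type
    transforms, rootfinding for the transcendental dispersion relation by
    delay continuation with a real-axis safeguard, Turing-space scans over
    the kinetic parameter plane, a method-of-lines delay-PDE simulator built
    on 'deSolve', and time-to-pattern metrics with cosine-mode amplitude
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
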