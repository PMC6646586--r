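Package: aecvision
Title: Active Efficient Coding of Binocular and Motion Vision
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates an active binocular vision agent that jointly learns a
    sparse spatio-temporal code for its visual input and the vergence and
    smooth-pursuit eye movements that make that code more efficient. Provides
    a pinhole-camera binocular renderer of a moving textured plane, retinal
    whitening and two-scale patch extraction, matching-pursuit sparse coding
    with learned dictionaries of binocular spatio-temporal basis functions,
    a natural actor-critic reinforcement learner driven by the negative
    reconstruction error, training and testing protocols, and receptive-field
    analyses (Gabor fitting, orientation, disparity and velocity tuning).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
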