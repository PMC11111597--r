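Package: voicescreen
Title: Voice-Based Screening for Cognitive Decline from Short Spoken Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rapid voice-based screen for cognitive decline equivalent to
    dementia. Recordings of a spoken time-orientation response are reduced to
    modulation-spectrum features of Mel-frequency cepstral coefficient
    trajectories; the response transcript is auto-scored 0-4 against the
    reference date; and a gradient-boosting classifier over age, task score
    and the 20 lower-order modulation-spectrum components predicts dementia
    versus cognitively normal. Includes the diagnostic-accuracy evaluation
    layer (confusion metrics with exact numerators and denominators, exact
    conditional 2x2 and r x c contingency-table tests, facility and
    age-decade stratification) and a synthetic-cohort generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
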