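# Shared fixtures, generated in code.

# a 1440x1080 pair with a 160x120 thermal grid (scale 1/9)
studyScalePair <- function(tempFill = 33) {
  makePair(rgbFrame(matrix(128, 1080, 1440)),
           thermalFrame(matrix(tempFill, 120, 160)))
}

# small thermal-size phantom config for fast Monte Carlo loops
fastNullConfig <- function(seed, ...) {
  phantomConfig(deltaTC = 0, seed = seed, ...)
}

# scores of one phantom record via the full pipeline
recordScore <- function(rec, nRows = 4, nCols = 4) {
  studyToScores(list(rec), nRows, nCols)
}
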