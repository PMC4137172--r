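# internal helpers

abort_bad_input <- function(msg, class = "surfaceomics_input_error") {
  abort(msg, class = class)
}

# Run code with a private RNG stream: seeds reproducibly, then restores the
# caller's .Random.seed so simulation calls do not disturb the session RNG.
with_private_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(abs(x - round(x)) < 1e-8)
}
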