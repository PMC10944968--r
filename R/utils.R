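# Seed substreams: every stochastic routine derives its own seed from the
# root seed plus a stream name, so that fixtures are reproducible and
# adding draws to one stage never perturbs another.
substream_seed <- function(root_seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(root_seed) * 69069 + h * 1013) %% .Machine$integer.max)
}

with_substream <- function(root_seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(root_seed, name))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
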