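# shared internal helpers

GENO_CODES <- c("AA", "AB", "BB")

# centre/scale a score; constant scores come back as all-zero with sd = 0 so
# callers can drop the term instead of dividing by ~0
std_score <- function(x) {
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) {
    list(z = rep(0, length(x)), mean = m, sd = 0)
  } else {
    list(z = (x - m) / s, mean = m, sd = s)
  }
}

# map functions: cM distance -> recombination fraction and back
mf_haldane <- function(d) 0.5 * (1 - exp(-d / 50))
imf_haldane <- function(r) -50 * log(1 - 2 * r)
mf_kosambi <- function(d) 0.5 * tanh(d / 50)
imf_kosambi <- function(r) 25 * log((1 + 2 * r) / (1 - 2 * r))

get_map_function <- function(name) {
  name <- match.arg(name, c("haldane", "kosambi"))
  switch(name,
    haldane = list(mf = mf_haldane, imf = imf_haldane),
    kosambi = list(mf = mf_kosambi, imf = imf_kosambi)
  )
}

normalize_cross_type <- function(cross_type) {
  key <- tolower(gsub("[^a-z0-9]", "", tolower(cross_type)))
  out <- switch(key,
    f2 = "f2",
    intercross = "f2",
    backcross = "backcross",
    bc = "backcross",
    riself = "riself",
    ril = "riself",
    selfedril = "riself",
    NULL
  )
  if (is.null(out)) {
    abort(paste0("unsupported cross type '", cross_type,
                 "' (expected one of f2, backcross, riself)"))
  }
  out
}

# n independent sub-seeds derived from one user seed (kept well below 2^31)
draw_seeds <- function(n, seed) {
  withr_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  out <- sample.int(2147483L * 1000L, n)
  if (!is.null(withr_seed)) assign(".Random.seed", withr_seed, envir = globalenv())
  out
}
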