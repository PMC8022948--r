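# Small deterministic fixtures shared across test files.

# single-chromosome map at the given positions
map1 <- function(pos, chr = "1") {
  genetic_map(chr = rep(chr, length(pos)),
              marker = paste0("m", seq_along(pos)), pos = pos)
}

# cross with fully specified integer genotypes on one chromosome
det_cross <- function(geno, pos, cross_type) {
  geno <- as.matrix(geno)
  colnames(geno) <- NULL
  cross_population(geno, map1(pos), cross_type)
}

# individuals on a line, unit spacing
line_smap <- function(n) {
  tibble::tibble(id = paste0("ind", seq_len(n)), x = seq_len(n), y = 0)
}

# a geno_probs object with hand-set deterministic probabilities
manual_gp <- function(prob, pos = seq_len(dim(prob)[2]) - 1,
                      cross_type = "f2") {
  n <- dim(prob)[1]
  grid <- insert_pseudomarkers(map1(pos), step = Inf)
  dimnames(prob) <- list(paste0("ind", seq_len(n)), grid$marker,
                         c("AA", "AB", "BB"))
  structure(
    list(prob = prob, grid = grid, cross_type = cross_type,
         error_prob = 0, map_function = "haldane",
         ids = paste0("ind", seq_len(n))),
    class = "geno_probs"
  )
}
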