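# Independent oracles used across the suite. These never call the package's
# alignment/superposition code paths they check.

# exhaustive enumeration of all global alignments under affine gaps
# (gap run of length L costs open + ext * L); returns the optimal score
enumerate_align_score <- function(a, b, sub, open, ext) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(a) && j > length(b)) return(0)
    best <- -Inf
    if (i <= length(a) && j <= length(b))
      best <- max(best, sub[a[i], b[j]] + rec(i + 1, j + 1, 0L))
    if (i <= length(a)) {
      cost <- if (state == 1L) ext else open + ext
      best <- max(best, -cost + rec(i + 1, j, 1L))
    }
    if (j <= length(b)) {
      cost <- if (state == 2L) ext else open + ext
      best <- max(best, -cost + rec(i, j + 1, 2L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# score the gapped alignment returned by global_align from its column
# vectors, charging each maximal gap run open + ext * L
score_alignment_columns <- function(map, a, b, sub, open, ext) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  total <- 0; gap_state <- 0L
  for (k in seq_along(map$col_a)) {
    ia <- map$col_a[k]; ib <- map$col_b[k]
    if (ia > 0L && ib > 0L) {
      total <- total + sub[a[ia], b[ib]]
      gap_state <- 0L
    } else if (ia > 0L) {            # gap in b
      total <- total - (if (gap_state == 1L) ext else open + ext)
      gap_state <- 1L
    } else {                         # gap in a
      total <- total - (if (gap_state == 2L) ext else open + ext)
      gap_state <- 2L
    }
  }
  total
}

# simple match/mismatch substitution matrix over an alphabet
mm_matrix <- function(match = 1, mismatch = -1,
                      alphabet = c("A", "C", "D", "E", "K")) {
  n <- length(alphabet)
  m <- matrix(mismatch, n, n, dimnames = list(alphabet, alphabet))
  diag(m) <- match
  m
}

# best rigid-fit RMSD by direct numerical minimization over rotations
# (Euler angles) and translations, independent of the SVD route
rmsd_by_optim <- function(A, B) {
  obj <- function(par) {
    cx <- cos(par[1]); sx <- sin(par[1])
    cy <- cos(par[2]); sy <- sin(par[2])
    cz <- cos(par[3]); sz <- sin(par[3])
    Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    R <- Rz %*% Ry %*% Rx
    Bf <- t(R %*% t(B))
    Bf <- sweep(Bf, 2, colMeans(Bf) - colMeans(A))
    sqrt(mean(rowSums((A - Bf)^2)))
  }
  best <- Inf
  for (s in 1:20) {
    set.seed(s)
    r <- optim(runif(3, -pi, pi), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, r$value)
  }
  best
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_aa <- function(n, alphabet = c("A", "C", "D", "E", "K")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# minimal fixed-width legacy PDB writer for CA-trace fixtures
toy_pdb_lines <- function(resno, resid, xyz, alt = rep(" ", length(resno)),
                          elety = rep("CA", length(resno)), chain = "A") {
  vapply(seq_along(resno), function(i) {
    sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            i, paste0(" ", elety[i]), alt[i], resid[i], chain, resno[i],
            xyz[i, 1], xyz[i, 2], xyz[i, 3], 1, 0)
  }, character(1))
}

write_toy_pdb <- function(path, resno, resid, xyz, ...) {
  writeLines(c(toy_pdb_lines(resno, resid, xyz, ...), "END"), path)
  path
}

# a small two-family analysis fixture built from explicit counts
counts_fixture <- function(mir, nbr) {
  cts <- mirenrich:::region_counts(mir, nbr)
  list(counts = cts, class = classify_domain(cts))
}
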