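# internal helpers

abort_undefined <- function(index, msg) {
  abort(msg, class = "intercrop_undefined_index", index = index)
}

# log-normal draw with arithmetic mean `mean` and coefficient of variation `cv`;
# cv = 0 degenerates to the constant mean
rlnorm_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# all permutations of 1:n as an n! x n integer matrix (lexicographic);
# used for the exact permutation null of the rank correlation
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 10)
  if (n == 1) return(matrix(1L, 1, 1))
  p <- all_permutations(n - 1)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- cbind(rep(i, nrow(p)), p + (p >= i))
  }
  do.call(rbind, out)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
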