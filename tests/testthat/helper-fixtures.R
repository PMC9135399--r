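# Shared small fixtures, all built in code.

tiny_db <- function() {
  complex_db(list(C1 = c("a", "b", "c"), C2 = c("c", "d")))
}

small_config <- function(seed = 1, ...) {
  cohort_config(n_samples_per_type = 60, n_genes = 440, n_complexes = 40,
                n_ppi_edges = 1200, n_tfs = 10, targets_per_tf = 20,
                seed = seed, ...)
}

# random 2x2 table with all margins positive
random_2x2 <- function() {
  repeat {
    tab <- matrix(sample(0:30, 4, replace = TRUE), 2)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0) && sum(tab) > 0) {
      return(tab)
    }
  }
}

# random complex list over a small protein alphabet
random_complexes <- function(n_cx = 10, alphabet = letters[1:12]) {
  cx <- lapply(seq_len(n_cx), function(i)
    sample(alphabet, sample(2:5, 1)))
  names(cx) <- paste0("C", seq_len(n_cx))
  cx
}

# KM survival estimate for a group at time t from a curves data.frame
km_at <- function(curves, group, t) {
  cc <- curves[curves$group == group & curves$time <= t, , drop = FALSE]
  if (!nrow(cc)) 1 else cc$surv[which.max(cc$time)]
}
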