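# Shared fixture builders for the test suite. All stochastic fixtures take
# an explicit seed so individual tests are reproducible in isolation.

# two well-separated Gaussian clusters in `p` dimensions
separable_set <- function(n = 20, p = 2, gap = 6, seed = 1) {
  withr::with_seed(seed, {
    n_pos <- n %/% 2
    x <- rbind(
      matrix(rnorm(n_pos * p, mean = gap / 2), ncol = p),
      matrix(rnorm((n - n_pos) * p, mean = -gap / 2), ncol = p)
    )
    colnames(x) <- paste0("f", seq_len(p))
    df <- dplyr::bind_cols(
      tibble::tibble(compound_id = sprintf("c%02d", seq_len(n))),
      tibble::as_tibble(x)
    )
    list(fm = feature_matrix(df, family = "toy"),
         labels = c(rep("hepatotoxic", n_pos),
                    rep("non_hepatotoxic", n - n_pos)))
  })
}

# feature matrix straight from a plain numeric matrix
fm_from_matrix <- function(x, ids = sprintf("c%02d", seq_len(nrow(x))),
                           value_kind = "continuous", family = "toy") {
  df <- dplyr::bind_cols(tibble::tibble(compound_id = ids),
                         tibble::as_tibble(x, .name_repair = "minimal"))
  feature_matrix(df, family = family, value_kind = value_kind)
}

# tiny CSV compound table on disk; returns the path
write_compound_csv <- function(rows, path = withr::local_tempfile(
  fileext = ".csv", .local_envir = parent.frame())) {
  readr::write_csv(rows, path, progress = FALSE)
  path
}
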