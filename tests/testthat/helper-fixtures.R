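# Shared fixtures: the seven-item instrument with unit discriminations and
# difficulties -2, -1, -.5, 0, .5, 1, 2 logits, and its worked response
# vector 1101110; plus the six-item vector 1,0,0,0,1,1.

items7 <- function() item_parameters(a = 1, b = c(-2, -1, -0.5, 0, 0.5, 1, 2))
respv9 <- function() c(1, 1, 0, 1, 1, 1, 0)
respv_case7 <- function() c(1, 0, 0, 0, 1, 1)

# all 2^J response vectors of length J as a matrix (row-wise)
all_vectors <- function(J) {
  m <- as.matrix(expand.grid(rep(list(0:1), J)))
  dimnames(m) <- NULL
  m
}

write_items_csv <- function(items, path) {
  df <- data.frame(a = items$a, b = items$b, k = items$k)
  if (any(is.finite(items$gamma))) df$gamma <- items$gamma
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

write_responses_csv <- function(m, path) {
  df <- as.data.frame(m)
  names(df) <- paste0("I", seq_len(ncol(m)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
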