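# brute-force oracle: enumerate all C(N, n) draws of the query from the
# universe and count those with at least k term carriers
enum_upper_tail <- function(k, n, K, N) {
  if (n == 0) return(if (k == 0) 1 else 0)
  draws <- utils::combn(N, n)
  carriers <- seq_len(K)
  hits <- colSums(matrix(draws %in% carriers, nrow = n))
  mean(hits >= k)
}
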