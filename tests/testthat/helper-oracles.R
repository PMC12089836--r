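# Independent AP oracle: exact area under the precision envelope, integrated
# between recall breakpoints from first principles. The envelope at recall r
# is the best precision achievable at recall >= r.
ap_bruteforce <- function(is_tp, n_gt) {
  tp <- cumsum(is_tp); fp <- cumsum(!is_tp)
  rec <- tp / n_gt; prec <- tp / (tp + fp)
  area <- 0; r_prev <- 0
  for (r in sort(unique(rec[rec > 0]))) {
    area <- area + (r - r_prev) * max(prec[rec >= r])
    r_prev <- r
  }
  area
}

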