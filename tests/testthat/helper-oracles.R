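# Independent forward mixing oracle: tabulates the moles of every isotope in
# the blood mixture explicitly and forms the ratios. Deliberately coded as a
# per-isotope ledger, distinct from the package's matrix/ratio formulation.
oracle_mix_ratios <- function(n_nat, n57, n58, nat, l57, l58,
                              base_r57 = NULL, base_r58 = NULL) {
  pools <- rbind(n_nat * unclass(nat), n57 * unclass(l57), n58 * unclass(l58))
  if (!is.null(base_r57)) {
    # native pool measured at calibrated baseline ratios
    pools[1, "a57"] <- n_nat * nat[["a56"]] * base_r57
    pools[1, "a58"] <- n_nat * nat[["a56"]] * base_r58
  }
  tot <- colSums(pools)
  c(r57 = tot[["a57"]] / tot[["a56"]], r58 = tot[["a58"]] / tot[["a56"]])
}

# random valid enriched composition, biased toward the given isotope
random_label <- function(main = c("a57", "a58")) {
  main <- match.arg(main)
  raw <- stats::runif(4, 0.001, 0.04)
  names(raw) <- c("a54", "a56", "a57", "a58")
  raw[main] <- stats::runif(1, 0.85, 0.99)
  raw <- raw / sum(raw)
  isotope_composition(raw[["a54"]], raw[["a56"]], raw[["a57"]], raw[["a58"]])
}
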