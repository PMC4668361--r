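# shared fixtures for the suite: small references and screen setups built in
# code so no binary data ships with the package

ref_kappa1 <- germline_fixture("kappa1")
ref_kappa4 <- germline_fixture("kappa4")
ref_vh3 <- germline_fixture("VH3")

# apply point substitutions (by Kabat number) to a germline sequence string
mutate_germline <- function(ref, numbers, to_aa) {
  aa <- ref$residues$aa
  idx <- match(numbers, ref$residues$number)
  stopifnot(!anyNA(idx))
  aa[idx] <- to_aa
  paste(aa, collapse = "")
}

# burial table marking a chosen set of Kabat numbers as buried and the rest
# exposed
burial_table <- function(ref, buried_numbers, rsa_buried = 0.05,
                         rsa_exposed = 0.7) {
  chain <- if (ref$chain_class == "heavy") "heavy" else "light"
  data.frame(
    chain = chain,
    number = ref$residues$number,
    rsa = ifelse(ref$residues$number %in% buried_numbers, rsa_buried,
                 rsa_exposed),
    stringsAsFactors = FALSE
  )
}

# the measured phenotype panel: WT plus three expression variants
panel_phenotypes <- function() {
  variant_phenotype(
    c("WT", "varA", "varB", "varC"),
    expression_fold = c(1, 3.7, 5.6, 7.2)
  )
}

expect_fraction_close <- function(x, target, tol) {
  expect_true(abs(x - target) <= tol,
              label = sprintf("%.4f within %.4f of %.4f", x, tol, target))
}
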