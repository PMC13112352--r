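## shared fixtures: the weak-polyacid test chain and E/K solution conditions

polyacid30 <- function() homopolymer("E", 30, pKa = c(E = 4.0))

acidParams <- function(pH, salt = 0.01)
  physicalParams(pH = pH, salt = salt, bjerrum = 7.1, kuhn = 5.8)

ekSpec <- function(n) sequenceSpec(ekVariant(n), omega = "volumes")

ekParams <- function(pH) physicalParams(pH = pH, salt = 0.015,
                                        bjerrum = 7.1, kuhn = 5.8)

## independent O(N^2) double-loop oracle for the SCD metric
scdLoop <- function(s) {
  r <- strsplit(s, "")[[1]]
  sigma <- ifelse(r %in% c("E", "D"), -1, ifelse(r %in% c("K", "R", "H"), 1, 0))
  N <- length(sigma)
  acc <- 0
  for (m in 2:N) for (n in 1:(m - 1))
    acc <- acc + sigma[m] * sigma[n] * sqrt(m - n)
  acc / N
}
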