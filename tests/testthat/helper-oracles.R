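# Independent oracle for the repeated-measures decomposition: explicit
# sums of squares from first principles.
brute_rm_anova <- function(scores) {
  s <- nrow(scores); k <- ncol(scores)
  grand <- mean(scores)
  ss_subject <- k * sum((rowMeans(scores) - grand)^2)
  ss_treat <- s * sum((colMeans(scores) - grand)^2)
  ss_total <- sum((scores - grand)^2)
  ss_error <- ss_total - ss_subject - ss_treat
  df1 <- k - 1
  df2 <- (k - 1) * (s - 1)
  F <- (ss_treat / df1) / (ss_error / df2)
  list(F = F, df1 = df1, df2 = df2,
       p = pf(F, df1, df2, lower.tail = FALSE))
}
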