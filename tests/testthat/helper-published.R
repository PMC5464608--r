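# The published worked example: 12 blinded samples (6 carriers, 6
# non-carriers) and the per-classifier calls, plus the 6 off-signature
# (Huntington's-model) samples appended for the 18-sample evaluation.
# C = carrier call, N = non-carrier call.
published_blind_test <- function() {
  actual <- c("N", "N", "N", "C", "C", "C", "N", "N", "N", "C", "C", "C")
  list(
    actual = actual,
    classifier1 = c("C", "N", "N", "C", "C", "C", "N", "C", "N", "C", "C", "C"),
    classifier2 = c("N", "N", "N", "C", "C", "C", "C", "N", "N", "C", "C", "C"),
    classifier3 = c("N", "N", "N", "N", "C", "C", "C", "N", "N", "C", "C", "C"))
}

# Off-signature samples are true non-carriers of the trained signature;
# per-classifier calls on them (classifiers 1 and 2 called all six
# non-carrier, classifier 3 called one carrier).
published_offsignature_calls <- function() {
  list(actual = rep("N", 6),
       classifier1 = rep("N", 6),
       classifier2 = rep("N", 6),
       classifier3 = c("N", "N", "N", "N", "N", "C"))
}

as_carrier <- function(x) ifelse(x == "C", "carrier", "non-carrier")

# Brute-force recount oracle, deliberately naive.
naive_confusion <- function(pred, act) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] && act[i]) tp <- tp + 1
    else if (pred[i] && !act[i]) fp <- fp + 1
    else if (!pred[i] && !act[i]) tn <- tn + 1
    else fn <- fn + 1
  }
  as.integer(c(tp, fp, tn, fn))
}

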