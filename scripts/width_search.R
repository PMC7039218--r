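#!/usr/bin/env Rscript
# Constrained integer search that froze the default EMGNet widths.
#
# The published contract is the total parameter budget (34311 learnable
# scalars for the 7-class model), not the per-layer widths.  This script
# enumerates nondecreasing widths for the four 3x3 body convolutions (biases
# on, per-channel PReLU slopes, 1x1 convolutional head with bias, 8 input
# channels) and prints every combination that meets the budget exactly.  The
# shipped default (18, 18, 43, 58) was chosen from this list because it also
# exercises both stride rules: layer 2 keeps its width (stride 1) while the
# other layers increase it (stride 2).
#
# Usage: Rscript scripts/width_search.R [n_classes] [budget]

args <- commandArgs(trailingOnly = TRUE)
n_classes <- if (length(args) >= 1) as.integer(args[1]) else 7L
budget <- if (length(args) >= 2) as.integer(args[2]) else 34311L
in_ch <- 8L

count_params <- function(w, per_channel_prelu = TRUE) {
  ins <- c(in_ch, w[1:3])
  conv <- sum(9L * ins * w + w)                      # weights + biases
  prelu <- if (per_channel_prelu) sum(w) else 4L
  head <- w[4] * n_classes + n_classes
  conv + prelu + head
}

hits <- NULL
for (w1 in 8:72) for (w2 in w1:112) for (w3 in w2:144) for (w4 in w3:192) {
  w <- c(w1, w2, w3, w4)
  if (count_params(w) == budget)
    hits <- rbind(hits, data.frame(w1 = w1, w2 = w2, w3 = w3, w4 = w4,
                                   params = budget))
}
if (is.null(hits)) {
  cat("no width combination meets the budget\n")
} else {
  print(hits, row.names = FALSE)
}
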