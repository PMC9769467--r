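#!/usr/bin/env Rscript
# Classify the 15 PUF variables by re-identification risk. Each variable
# carries expert scores for replicability, availability and
# distinguishability (1..3); variables with a total above 5 are key
# variables (quasi-identifiers) protected by k-anonymity, the rest are
# sensitive and protected by t-closeness — except the two variables that
# are perfectly correlated with other sensitive variables and therefore
# implicitly protected.

suppressPackageStartupMessages(library(pufanon))
dir.create("results", showWarnings = FALSE)

ratings <- default_variable_ratings()
tri <- triage(ratings)

out <- merge(ratings, tri$scores, by = "variable", sort = FALSE)
out$class <- ifelse(out$variable %in% tri$key_variables, "key",
                    ifelse(out$variable %in% tri$implicit_variables,
                           "implicit", "sensitive"))
out <- out[match(puf_variables(), out$variable), ]
write.csv(out, "results/variable_triage.csv", row.names = FALSE)

cat("key variables: ", paste(tri$key_variables, collapse = ", "), "\n")
cat("sensitive:     ", paste(tri$sensitive_variables, collapse = ", "), "\n")
cat("implicit:      ", paste(tri$implicit_variables, collapse = ", "), "\n")
cat("wrote results/variable_triage.csv\n")
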