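#!/usr/bin/env Rscript
# Stage 4: geometric comparison of the six G matrices.
#
# Krzanowski common-subspace analysis (do the leading directions of genetic
# variance coincide?), the fourth-order covariance tensor (which trait
# combinations differ most among populations?), and random skewers (do the
# matrices answer random selection the same way?), each judged against the
# permutation nulls from stage 3.

suppressPackageStartupMessages(library(halfsibG))

G_by_pop <- readRDS("results/G_by_pop.rds")
null_G <- readRDS("results/null_G.rds")
p <- length(G_by_pop)

krz <- krzanowski_subspace(G_by_pop, null_G = null_G)
cat("Krzanowski H eigenvalues (bound =", p, "populations):\n")
for (i in seq_len(krz$n_traits))
  cat(sprintf("  rank %d: %.2f [%.2f, %.2f]  null [%.2f, %.2f]%s\n", i,
              krz$eig_mean[i], krz$eig_hpd[1, i], krz$eig_hpd[2, i],
              krz$null_hpd[1, i], krz$null_hpd[2, i],
              ifelse(isTRUE(krz$diverged[i]), "  <- diverged", "")))

tens <- covariance_tensor(G_by_pop, null_G = null_G)
cat("covariance tensor: leading eigentensor variance shares (alpha):\n")
for (i in 1:4) {
  cat(sprintf("  E%d: alpha = %.2f [%.2f, %.2f]  null [%.2f, %.2f]%s\n", i,
              tens$alpha_mean[i], tens$alpha_hpd[1, i], tens$alpha_hpd[2, i],
              tens$null_alpha_hpd[1, i], tens$null_alpha_hpd[2, i],
              ifelse(isTRUE(tens$significant[i]), "  <- significant", "")))
  shares <- tens$tensor_eigen[[i]]$variance_share
  cat(sprintf("      leading trait combination explains %.0f%% of E%d\n",
              100 * shares[1], i))
}

skw <- random_skewers(G_by_pop, n_skewers = 1000, seed = 303,
                      summary = "draws")
cat("random skewers: pairwise response-vector correlations\n")
cat(sprintf("  range %.2f .. %.2f over %d pairs (1 = identical response)\n",
            min(skw$pairs$correlation), max(skw$pairs$correlation),
            nrow(skw$pairs)))

write.csv(data.frame(rank = seq_len(krz$n_traits), eigenvalue = krz$eig_mean,
                     hpd_low = krz$eig_hpd[1, ], hpd_high = krz$eig_hpd[2, ],
                     null_low = krz$null_hpd[1, ],
                     null_high = krz$null_hpd[2, ],
                     diverged = krz$diverged),
          "results/krzanowski.csv", row.names = FALSE)
write.csv(data.frame(eigentensor = seq_along(tens$alpha_mean),
                     alpha = tens$alpha_mean,
                     hpd_low = tens$alpha_hpd[1, ],
                     hpd_high = tens$alpha_hpd[2, ],
                     null_low = tens$null_alpha_hpd[1, ],
                     null_high = tens$null_alpha_hpd[2, ],
                     significant = tens$significant),
          "results/tensor_alpha.csv", row.names = FALSE)
write.csv(skw$pairs, "results/skewers.csv", row.names = FALSE)
cat("wrote results/{krzanowski,tensor_alpha,skewers}.csv\n")
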