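# Shared fixtures: tiny deterministic images, masks and stub models.

rand_u8 <- function(nr, nc) matrix(sample(0:255, nr * nc, TRUE), nr, nc)

# Brute-force Otsu sweep over all 255 cut points (the independent oracle
# for otsu_binary): background = levels <= t, foreground = levels > t.
# Returns every cut attaining the maximal between-class variance (empty
# histogram bins produce plateaus of equivalent cuts).
oracle_otsu <- function(px) {
  h <- tabulate(px + 1, 256); n <- sum(h); lev <- 0:255
  v <- rep(-1, 255)
  for (t in 0:254) {
    w0 <- sum(h[1:(t + 1)]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(h[1:(t + 1)] * lev[1:(t + 1)]) / w0
    m1 <- sum(h[(t + 2):256] * lev[(t + 2):256]) / w1
    v[t + 1] <- w0 * w1 * (m0 - m1)^2
  }
  which(v == max(v)) - 1
}

# Independent greedy re-run used as the gd_search oracle: full candidate
# enumeration at every step, recursion instead of the package's loop.
oracle_gd <- function(raw, mask, target, step0 = 0.10, dec = 0.01,
                      ops = c("contrast", "brightness", "gamma")) {
  dist_of <- function(chain) {
    adj <- render_chain(raw, chain, quantize = FALSE)
    metric_distance(extract_metric(adj, mask,
                                   use_std = !is.null(target$bg_std)),
                    target)
  }
  chain <- adjust_chain()
  d <- dist_of(chain)
  s <- round(step0 * 100)
  while (s >= 1) {
    cands <- list()
    for (op in ops) for (sg in c(+1, -1)) {
      amt <- if (op == "gamma") 1 + sg * s / 100 else sg * s / 100
      cands[[length(cands) + 1]] <- list(op = op, amount = amt)
    }
    dc <- vapply(cands, function(cd)
      dist_of(semprep:::chain_append(chain, cd$op, cd$amount)), numeric(1))
    if (min(dc) < d - 1e-9) {
      k <- which.min(dc)
      chain <- semprep:::chain_append(chain, cands[[k]]$op,
                                      cands[[k]]$amount)
      d <- dc[k]
    } else s <- s - round(dec * 100)
  }
  list(chain = chain, distance = d)
}

# Oracle segmenter: a function window -> probability array that encodes
# a fixed full-section class map, looked up by matching window content is
# impossible, so tests instead use the function-model interface of
# predict_section with intensity-defined rules.
probs_from_labels <- function(labels) {
  out <- array(0, c(nrow(labels), ncol(labels), 3))
  for (k in 0:2) out[, , k + 1][labels == k] <- 1
  out
}

# A clean (identity-perturbation, noiseless) cohort spec for search and
# bootstrap tests.
clean_spec <- function(size = 128L, seed = 1L)
  cohort_spec(n_sections = 1L, section_size = size,
              gamma_range = c(1, 1), brightness_range = c(0, 0),
              noise_sd = 0, seed = seed)
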