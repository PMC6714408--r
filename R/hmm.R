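#' Hidden Markov model for copy-number decoding from LRR/BAF
#'
#' Constructs the HMM used by [viterbi_decode()]. States are integer copy
#' numbers 0--4. Each state emits a log R ratio (LRR) from a Normal with a
#' state-specific mean and SD, and a B-allele frequency (BAF) from a mixture
#' of truncated Normals whose cluster means reflect the allelic compositions
#' possible at that copy number (CN1: 0, 1; CN2: 0, 1/2, 1; CN3: thirds;
#' CN4: quarters; CN0: no allelic signal, BAF uniform). Mixture weights come
#' from the probe's population B-allele frequency (PFB). Clusters at 0 and 1
#' use a narrower boundary SD because hybridization pins BAF to the rails.
#'
#' Transitions depend on the physical distance between adjacent probes:
#' the total probability of leaving the current state is
#' `base_transition_prob * (1 - exp(-distance / distance_scale_d))`,
#' shared equally among the four other states, so distant probes are nearly
#' independent while dense probes strongly favour staying in state.
#'
#' @param lrr_means numeric(5), LRR emission means for CN 0..4. Must be
#'   strictly increasing for CN >= 1.
#' @param lrr_sds numeric(5), LRR emission SDs for CN 0..4.
#' @param baf_sd SD of interior BAF clusters (means strictly inside (0,1)).
#' @param baf_boundary_sd SD of the boundary clusters at BAF 0 and 1.
#' @param base_transition_prob asymptotic probability of a state change
#'   between infinitely distant probes, in (0, 1).
#' @param distance_scale_d distance scale (bp) of the transition decay.
#' @param start_cn2_prob initial-state probability of CN = 2; the remainder
#'   is split uniformly over the other four states.
#' @param min_sd floor applied to all SDs to keep densities finite.
#' @return An object of class `hmm_model`.
#' @examples
#' m <- hmm_model()
#' emission_loglik(lrr = 0, baf = 0.5, pfb = 0.5, state = 2, model = m)
#' @export
hmm_model <- function(lrr_means = c(-3.5, -0.66, 0, 0.40, 0.68),
                      lrr_sds = c(1.00, 0.25, 0.15, 0.20, 0.25),
                      baf_sd = 0.05,
                      baf_boundary_sd = 0.02,
                      base_transition_prob = 0.2,
                      distance_scale_d = 1e5,
                      start_cn2_prob = 0.99,
                      min_sd = 1e-4) {
  stopifnot(length(lrr_means) == 5, length(lrr_sds) == 5)
  if (any(diff(lrr_means[-1]) <= 0))
    stop("lrr_means must be strictly increasing for CN >= 1")
  if (base_transition_prob <= 0 || base_transition_prob >= 1)
    stop("base_transition_prob must be in (0, 1)")
  if (distance_scale_d <= 0) stop("distance_scale_d must be positive")
  if (start_cn2_prob <= 0 || start_cn2_prob >= 1)
    stop("start_cn2_prob must be in (0, 1)")
  structure(list(
    states = 0:4,
    lrr_means = lrr_means,
    lrr_sds = pmax(lrr_sds, min_sd),
    baf_sd = max(baf_sd, min_sd),
    baf_boundary_sd = max(baf_boundary_sd, min_sd),
    base_transition_prob = base_transition_prob,
    distance_scale_d = distance_scale_d,
    start_cn2_prob = start_cn2_prob
  ), class = "hmm_model")
}

# Truncated-Normal density on [0, 1]; vectorized over mean/sd.
dtnorm01 <- function(x, mean, sd) {
  z <- stats::pnorm(1, mean, sd) - stats::pnorm(0, mean, sd)
  d <- stats::dnorm(x, mean, sd) / z
  d[x < 0 | x > 1] <- 0
  d
}

#' BAF cluster means and mixture weights for a copy-number state
#'
#' At copy number c the possible B-allele counts are 0..c, giving cluster
#' means b/c; under random allele draws at population B-allele frequency
#' `pfb` the weights are Binomial(c, pfb). CN 0 has no clusters (uniform
#' BAF).
#'
#' @param state integer copy number in 0..4.
#' @param pfb population B-allele frequency in \[0, 1\].
#' @return list with `means` and `weights` (empty for CN 0).
#' @export
baf_clusters <- function(state, pfb) {
  stopifnot(state %in% 0:4, pfb >= 0, pfb <= 1)
  if (state == 0L) return(list(means = numeric(0), weights = numeric(0)))
  k <- 0:state
  list(means = k / state, weights = stats::dbinom(k, state, pfb))
}

#' Per-probe emission log-likelihood
#'
#' Log of `Normal(lrr; mu_state, sd_state) * BAFmix(baf; state, pfb)` where
#' BAFmix is the PFB-weighted mixture of truncated Normals described in
#' [hmm_model()]. Always finite: the density is floored far below any
#' realistic likelihood so that a single wild probe cannot produce -Inf.
#'
#' @param lrr log R ratio at the probe.
#' @param baf B-allele frequency at the probe, clipped to \[0, 1\].
#' @param pfb population B-allele frequency of the probe.
#' @param state integer copy number in 0..4.
#' @param model an [hmm_model()].
#' @return scalar log-likelihood (finite).
#' @export
emission_loglik <- function(lrr, baf, pfb, state, model) {
  stopifnot(inherits(model, "hmm_model"), state %in% 0:4)
  baf <- min(max(baf, 0), 1)
  ll_lrr <- stats::dnorm(lrr, model$lrr_means[state + 1L],
                         model$lrr_sds[state + 1L], log = TRUE)
  if (state == 0L) {
    dens_baf <- 1  # deleted both copies: BAF carries no allelic signal
  } else {
    cl <- baf_clusters(state, pfb)
    sds <- ifelse(cl$means == 0 | cl$means == 1,
                  model$baf_boundary_sd, model$baf_sd)
    dens_baf <- sum(cl$weights * dtnorm01(baf, cl$means, sds))
  }
  max(ll_lrr, -700) + log(max(dens_baf, 1e-300))
}

#' Distance-dependent transition probability between copy-number states
#'
#' @param distance inter-probe distance in bp (>= 1).
#' @param from_state,to_state integer copy numbers in 0..4.
#' @param model an [hmm_model()].
#' @return transition probability; each row of the implied matrix sums to 1.
#' @export
transition_prob <- function(distance, from_state, to_state, model) {
  stopifnot(inherits(model, "hmm_model"), distance >= 1,
            from_state %in% 0:4, to_state %in% 0:4)
  off <- model$base_transition_prob * (1 - exp(-distance / model$distance_scale_d))
  if (from_state == to_state) 1 - off else off / 4
}

# 5x5 log-transition matrix at one inter-probe distance.
log_transition_matrix <- function(distance, model) {
  off <- model$base_transition_prob * (1 - exp(-distance / model$distance_scale_d))
  m <- matrix(off / 4, 5, 5)
  diag(m) <- 1 - off
  log(m)
}

log_start_probs <- function(model) {
  p <- rep((1 - model$start_cn2_prob) / 4, 5)
  p[3] <- model$start_cn2_prob
  log(p)
}

#' Viterbi decoding of the copy-number state path
#'
#' Computes the jointly most probable copy-number path for the ordered
#' probes of one chromosome, in log space, under the start distribution,
#' [transition_prob()] and [emission_loglik()] of `model`.
#'
#' @param signals data.frame with columns `position`, `lrr`, `baf`, `pfb`,
#'   sorted by position, all on one chromosome.
#' @param model an [hmm_model()].
#' @return integer vector of decoded copy numbers (0..4), one per probe,
#'   with attribute `logp` holding the log joint probability of the path.
#' @export
viterbi_decode <- function(signals, model) {
  stopifnot(inherits(model, "hmm_model"))
  n <- nrow(signals)
  if (is.null(n) || n < 1) stop("viterbi_decode: need at least one probe")
  if (is.unsorted(signals$position, strictly = TRUE))
    stop("viterbi_decode: probe positions must be strictly increasing")
  emis <- matrix(0, n, 5)
  for (i in seq_len(n))
    for (s in 0:4)
      emis[i, s + 1L] <- emission_loglik(signals$lrr[i], signals$baf[i],
                                         signals$pfb[i], s, model)
  delta <- log_start_probs(model) + emis[1, ]
  back <- matrix(0L, n, 5)
  if (n > 1) {
    for (i in 2:n) {
      lt <- log_transition_matrix(signals$position[i] - signals$position[i - 1L],
                                  model)
      cand <- delta + lt  # rows: from, cols: to
      back[i, ] <- max.col(t(cand), ties.method = "first")
      delta <- cand[cbind(back[i, ], 1:5)] + emis[i, ]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  if (n > 1) for (i in n:2) path[i - 1L] <- back[i, path[i]]
  structure(as.integer(path - 1L), logp = max(delta))
}

#' Turn a decoded state path into CNV calls
#'
#' Maximal runs of constant copy number different from 2 become calls whose
#' start/end are the first/last probe positions of the run. Runs supported
#' by three or fewer probes are discarded (calls must be supported by more
#' than three SNPs).
#'
#' @param path integer copy-number path from [viterbi_decode()].
#' @param signals the probe data.frame the path was decoded from; needs
#'   columns `position` and `name` (probe identifiers).
#' @param sample_id,chromosome identifiers stamped on every call.
#' @param min_snps minimum probes per retained call (default 4).
#' @return data.frame of calls with columns `sample_id`, `chromosome`,
#'   `start`, `end`, `copy_number`, `num_snps`, `start_probe`, `end_probe`.
#' @export
calls_from_path <- function(path, signals, sample_id = "S1",
                            chromosome = "1", min_snps = 4L) {
  if (length(path) != nrow(signals))
    stop("path and signals must have the same length")
  r <- rle(as.integer(path))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 2L & r$lengths >= min_snps
  empty_calls(
    sample_id = rep(sample_id, sum(keep)),
    chromosome = rep(as.character(chromosome), sum(keep)),
    start = signals$position[starts[keep]],
    end = signals$position[ends[keep]],
    copy_number = r$values[keep],
    num_snps = r$lengths[keep],
    start_probe = as.character(signals$name[starts[keep]]),
    end_probe = as.character(signals$name[ends[keep]])
  )
}

# Canonical calls data.frame constructor (zero rows when called empty).
empty_calls <- function(sample_id = character(0), chromosome = character(0),
                        start = integer(0), end = integer(0),
                        copy_number = integer(0), num_snps = integer(0),
                        start_probe = character(0), end_probe = character(0)) {
  data.frame(sample_id = as.character(sample_id),
             chromosome = as.character(chromosome),
             start = as.numeric(start), end = as.numeric(end),
             copy_number = as.integer(copy_number),
             num_snps = as.integer(num_snps),
             start_probe = as.character(start_probe),
             end_probe = as.character(end_probe),
             stringsAsFactors = FALSE)
}

#' Call CNVs for one sample from probe-level signal
#'
#' Runs [viterbi_decode()] independently per chromosome (autosomes only by
#' default) and converts the decoded paths to calls with
#' [calls_from_path()].
#'
#' @param signal data.frame with columns `probe`, `lrr`, `baf` for one
#'   sample.
#' @param probe_map data.frame with columns `name`, `chromosome`,
#'   `position`, `pfb`, sorted by (chromosome, position).
#' @param model an [hmm_model()].
#' @param sample_id identifier stamped on the calls.
#' @param autosomes_only drop chromosomes X/Y/MT before decoding.
#' @param min_snps minimum probes per retained call.
#' @return calls data.frame (see [calls_from_path()]).
#' @export
call_cnvs <- function(signal, probe_map, model = hmm_model(),
                      sample_id = "S1", autosomes_only = TRUE,
                      min_snps = 4L) {
  df <- merge(signal, probe_map, by.x = "probe", by.y = "name")
  if (autosomes_only)
    df <- df[!toupper(df$chromosome) %in% c("X", "Y", "MT", "M"), ]
  out <- list()
  for (chr in unique(df$chromosome)) {
    d <- df[df$chromosome == chr, ]
    d <- d[order(d$position), ]
    sig <- data.frame(name = d$probe, position = d$position,
                      lrr = d$lrr, baf = d$baf, pfb = d$pfb)
    path <- viterbi_decode(sig, model)
    out[[chr]] <- calls_from_path(path, sig, sample_id, chr, min_snps)
  }
  if (!length(out)) return(empty_calls())
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Exclude samples with an excessive number of CNV calls
#'
#' Samples carrying more than `max_calls` calls are removed; their
#' genome-wide signal is considered unreliable.
#'
#' @param calls calls data.frame with a `sample_id` column.
#' @param sample_ids all samples under study (samples with zero calls are
#'   kept); defaults to the samples present in `calls`.
#' @param max_calls exclusion threshold: strictly more than this many calls
#'   excludes the sample (default 100).
#' @return list with `calls` (calls of kept samples), `kept` (sample ids),
#'   and `excluded` (data.frame of excluded sample ids and their call
#'   counts).
#' @export
sample_cnv_qc <- function(calls, sample_ids = unique(calls$sample_id),
                          max_calls = 100L) {
  counts <- table(factor(calls$sample_id, levels = sample_ids))
  bad <- names(counts)[counts > max_calls]
  list(calls = calls[!calls$sample_id %in% bad, , drop = FALSE],
       kept = setdiff(sample_ids, bad),
       excluded = data.frame(sample_id = bad,
                             n_calls = as.integer(counts[bad]),
                             stringsAsFactors = FALSE))
}
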