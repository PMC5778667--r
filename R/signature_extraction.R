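# Extraction of treatment-associated mutational signatures from
# treated/control preclinical replicate experiments.
#
# Replicate counts in context j follow C_ij ~ Poisson(B_j + t_i * T_j) with
# flat nonnegative priors on the background rates B and treatment rates T.
# The treatment excess T, normalised and adjusted for genome trinucleotide
# composition, is the treatment-associated signature.

#' Build a preclinical experiment set
#'
#' Holds the per-replicate 96-channel mutation counts of a treated/control
#' mutagenesis experiment, plus (optionally) the genome trinucleotide
#' composition of the model organism and of human, used later by
#' [genome_normalize()].
#'
#' @param counts Numeric matrix, one row per replicate experiment, 96 columns
#'   in [sbs_contexts()] order.
#' @param treated Logical (or 0/1) vector flagging treated replicates. At
#'   least one treated and one control row are required.
#' @param human_trinuc_freq,organism_trinuc_freq Optional named 32-vectors over
#'   [trinucleotides_32()] (see [count_trinucleotide_freq()]); all entries
#'   must be positive.
#' @return An object of class `experiment_set`.
#' @export
experiment_set <- function(counts, treated,
                           human_trinuc_freq = NULL,
                           organism_trinuc_freq = NULL) {
  counts <- as.matrix(counts)
  treated <- as.logical(treated)
  if (ncol(counts) != 96L) stop("counts must have 96 columns")
  if (nrow(counts) != length(treated)) {
    stop("one treated flag is required per experiment row")
  }
  if (any(counts < 0) || any(is.na(counts))) stop("counts must be nonnegative")
  if (!any(treated) || all(treated)) {
    stop("cannot separate background from treatment: need both treated and control rows")
  }
  check_freq <- function(f, what) {
    if (is.null(f)) return(NULL)
    if (is.null(names(f))) {
      if (length(f) != 32L) stop(what, " must have 32 entries")
      names(f) <- trinucleotides_32()
    }
    if (!all(trinucleotides_32() %in% names(f))) {
      stop(what, " must be named by the 32 pyrimidine-centred trinucleotides")
    }
    if (any(f <= 0)) stop(what, " must be strictly positive")
    f[trinucleotides_32()]
  }
  colnames(counts) <- sbs_contexts()
  structure(
    list(
      counts = counts, treated = treated,
      human_trinuc_freq = check_freq(human_trinuc_freq, "human_trinuc_freq"),
      organism_trinuc_freq = check_freq(organism_trinuc_freq, "organism_trinuc_freq")
    ),
    class = "experiment_set"
  )
}

#' @export
print.experiment_set <- function(x, ...) {
  cat("<experiment_set> ", nrow(x$counts), " replicates (",
      sum(x$treated), " treated, ", sum(!x$treated), " control), ",
      sum(x$counts), " mutations\n", sep = "")
  invisible(x)
}

# Exact maximizer of the per-channel Poisson likelihood under B, T >= 0.
# The log-likelihood is concave in (B, T). Interior stationary point:
# B = control mean, T = treated mean - control mean, valid when nonnegative.
# When the treated mean falls below the control mean the maximum sits on the
# T = 0 boundary, where B profiles to the pooled mean of all rows.
.map_fit <- function(counts, treated) {
  mc <- colMeans(counts[!treated, , drop = FALSE])
  mt <- colMeans(counts[treated, , drop = FALSE])
  pooled <- colMeans(counts)
  excess <- mt >= mc
  B <- ifelse(excess, mc, pooled)
  T <- pmax(mt - mc, 0)
  list(background = B, treatment = T)
}

.mcmc_fit <- function(counts, treated, n_iter, n_burn, seed) {
  if (!requireNamespace("rjags", quietly = TRUE)) {
    stop("method = \"mcmc\" requires the rjags package")
  }
  model_str <- "
    model {
      for (i in 1:n) {
        for (j in 1:m) {
          C[i, j] ~ dpois(B[j] + t[i] * T[j] + 1e-10)
        }
      }
      for (j in 1:m) {
        B[j] ~ dunif(0, U)
        T[j] ~ dunif(0, U)
      }
    }"
  upper <- max(counts) * 10 + 50
  inits <- list(
    B = pmax(colMeans(counts[!treated, , drop = FALSE]), 0.01),
    T = pmax(colMeans(counts[treated, , drop = FALSE]) -
               colMeans(counts[!treated, , drop = FALSE]), 0.01),
    .RNG.name = "base::Mersenne-Twister",
    .RNG.seed = if (is.null(seed)) 1L else as.integer(seed)
  )
  jm <- rjags::jags.model(
    textConnection(model_str),
    data = list(C = counts, t = as.integer(treated),
                n = nrow(counts), m = ncol(counts), U = upper),
    inits = inits, n.chains = 1L, quiet = TRUE
  )
  update(jm, n_burn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("B", "T"), n.iter = n_iter,
                              progress.bar = "none")[[1L]]
  m <- ncol(counts)
  Bcols <- paste0("B[", seq_len(m), "]")
  Tcols <- paste0("T[", seq_len(m), "]")
  qs <- apply(samp, 2L, stats::quantile, probs = c(0.025, 0.975))
  list(
    background = colMeans(samp[, Bcols, drop = FALSE]),
    treatment = colMeans(samp[, Tcols, drop = FALSE]),
    uncertainty = list(
      background_ci = t(qs[, Bcols, drop = FALSE]),
      treatment_ci = t(qs[, Tcols, drop = FALSE])
    )
  )
}

#' Fit the Poisson background/treatment model
#'
#' Separates replicate mutation counts into per-channel background rates
#' \eqn{B_j} and treatment-associated rates \eqn{T_j} under the model
#' \eqn{C_{ij} \sim Poisson(B_j + t_i T_j)} with flat nonnegative priors.
#' Channels are independent.
#'
#' `method = "map"` returns the exact maximizer of the likelihood: when the
#' treated mean exceeds the control mean, \eqn{B_j} is the control mean and
#' \eqn{T_j} the excess; otherwise \eqn{T_j = 0} and \eqn{B_j} is the pooled
#' mean (the boundary maximum of the concave log-likelihood). Negative excess
#' is never returned, as the model constrains rates to be nonnegative.
#'
#' `method = "mcmc"` draws from the posterior with JAGS and returns posterior
#' means plus 95% credible intervals; posterior means approach the MAP fit as
#' counts grow.
#'
#' @param experiments An [experiment_set()].
#' @param method `"map"` (default, deterministic) or `"mcmc"`.
#' @param n_iter,n_burn MCMC sampling and burn-in lengths.
#' @param seed RNG seed for the sampler (ignored for `"map"`).
#' @return An object of class `treatment_fit` with elements `background`,
#'   `treatment` (named 96-vectors) and `uncertainty` (NULL for `"map"`).
#' @export
fit_treatment_model <- function(experiments, method = c("map", "mcmc"),
                                n_iter = 4000, n_burn = 1000, seed = NULL) {
  stopifnot(inherits(experiments, "experiment_set"))
  method <- match.arg(method)
  fit <- if (method == "map") {
    c(.map_fit(experiments$counts, experiments$treated), list(uncertainty = NULL))
  } else {
    .mcmc_fit(experiments$counts, experiments$treated, n_iter, n_burn, seed)
  }
  names(fit$background) <- names(fit$treatment) <- sbs_contexts()
  structure(
    list(background = fit$background, treatment = fit$treatment,
         uncertainty = fit$uncertainty, method = method),
    class = "treatment_fit"
  )
}

#' @export
print.treatment_fit <- function(x, ...) {
  cat("<treatment_fit> method=", x$method,
      "  sum(B)=", round(sum(x$background), 2),
      "  sum(T)=", round(sum(x$treatment), 2), "\n", sep = "")
  invisible(x)
}

#' Convert a treatment effect into a genome-adjusted signature
#'
#' Normalises the fitted treatment rates and adjusts each channel by the ratio
#' of human to model-organism genome abundance of its reference trinucleotide:
#' \deqn{N_j = (T_j / \sum_{j'} T_{j'}) (h_j / m_j)}
#' where \eqn{h_j} and \eqn{m_j} are the occurrences of the reference
#' trinucleotide of channel \eqn{j} in the human and model genomes. The result
#' is renormalised to sum to one so it can serve as a probability vector in a
#' signature catalogue; the adjustment is invariant to rescaling of `T`.
#'
#' @param fit A `treatment_fit`.
#' @param human_freq,organism_freq Named 32-vectors over
#'   [trinucleotides_32()]; defaults are taken from the experiment set if it
#'   carried them.
#' @return Named numeric 96-vector summing to 1.
#' @export
genome_normalize <- function(fit, human_freq, organism_freq) {
  stopifnot(inherits(fit, "treatment_fit"))
  T <- fit$treatment
  if (sum(T) <= 0) stop("no treatment effect to normalize (sum(T) = 0)")
  h <- human_freq[context_trinucleotides()]
  m <- organism_freq[context_trinucleotides()]
  if (any(is.na(h)) || any(is.na(m))) {
    stop("frequency vectors must be named by the 32 pyrimidine-centred trinucleotides")
  }
  if (any(m <= 0) || any(h <= 0)) stop("trinucleotide frequencies must be positive")
  N <- (T / sum(T)) * (as.numeric(h) / as.numeric(m))
  stats::setNames(N / sum(N), sbs_contexts())
}

#' Cosine similarity between two signatures
#'
#' @param a,b Numeric vectors of equal length (typically 96-channel
#'   signatures). Both must be nonzero.
#' @return Cosine similarity in `[0, 1]` for nonnegative inputs; 1 indicates
#'   proportional vectors.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Read an experiments CSV into an experiment set
#'
#' Expected layout: one row per replicate with columns `experiment_id`,
#' `treated` (0/1 or logical), then the 96 context-count columns named by
#' [sbs_contexts()].
#'
#' @param path CSV path.
#' @return An [experiment_set()].
#' @export
read_experiments_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(sbs_contexts(), names(df))
  if (length(missing)) {
    stop("experiments file lacks context columns, e.g. ", missing[1L])
  }
  experiment_set(as.matrix(df[, sbs_contexts()]),
                 treated = as.logical(as.integer(df$treated)))
}

#' Read / write trinucleotide-frequency CSVs
#'
#' Layout: columns `trinucleotide`, `count` covering the 32
#' pyrimidine-centred trinucleotides.
#'
#' @param path CSV path.
#' @return Named numeric 32-vector.
#' @export
read_trinuc_freq_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(trinucleotides_32() %in% df$trinucleotide)) {
    stop("frequency file must cover the 32 pyrimidine-centred trinucleotides")
  }
  stats::setNames(df$count[match(trinucleotides_32(), df$trinucleotide)],
                  trinucleotides_32())
}

#' @rdname read_trinuc_freq_csv
#' @param freq Named 32-vector (see [count_trinucleotide_freq()]).
#' @export
write_trinuc_freq_csv <- function(freq, path) {
  utils::write.csv(
    data.frame(trinucleotide = names(freq), count = as.numeric(freq)),
    path, row.names = FALSE
  )
}

#' Write a single signature to CSV
#'
#' 96 rows with columns `context` and the signature's probability, matching
#' one column of the catalogue layout.
#'
#' @param signature Named 96-vector (e.g. from [genome_normalize()]).
#' @param path Output path.
#' @param name Column name for the probability column.
#' @export
write_signature_csv <- function(signature, path, name = "signature") {
  df <- data.frame(context = sbs_contexts(),
                   p = as.numeric(signature[sbs_contexts()]))
  names(df)[2L] <- name
  utils::write.csv(df, path, row.names = FALSE)
}
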