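#' Simulate a random phylogeny over microbial features
#'
#' Pure-birth (Yule) topology with independent exponential branch lengths;
#' leaves are labelled `f1..fp`. All pairwise cophenetic distances are
#' positive because every branch length is strictly positive almost surely.
#'
#' @param n_features number of leaves (>= 2).
#' @param branch_rate rate of the exponential branch-length distribution
#'   (default 1; mean branch length `1/branch_rate`).
#' @param seed optional integer seed (R's RNG state is restored afterwards).
#' @return an [ape::phylo] tree.
#' @export
simulate_tree <- function(n_features, branch_rate = 1, seed = NULL) {
  if (n_features < 2L) stop_validation("'n_features' must be >= 2")
  with_rng_seed(seed, {
    tree <- ape::rphylo(n_features, birth = 1, death = 0)
    tree$edge.length <- stats::rexp(nrow(tree$edge), rate = branch_rate)
    tree$tip.label <- paste0("f", seq_len(n_features))
    tree
  })
}

#' Simulate a microbiome-like dataset with clade-localized signal
#'
#' Emulates the data regime phylogeny-informed forests target: a random
#' phylogeny, a highly skewed zero-inflated abundance table, and an outcome
#' driven by the features of one clade. Abundances are drawn per cell from a
#' log-normal distribution, Bernoulli-masked to zero with probability
#' `zero_prob`, row-normalized to a relative profile, and multiplied by a
#' per-sample library size uniform on `lib_size_range` (then rounded) to
#' give counts. The signal summary is the summed relative abundance of the
#' signal features, standardized across samples; classification outcomes
#' are Bernoulli with logit `effect_size * z`, regression outcomes are
#' `effect_size * z` plus Gaussian noise.
#'
#' The signal clade is the clade whose leaf count is closest to
#' `signal_fraction * n_features` (an error is raised if no clade comes
#' within 50% of that target); `signal_mode = "scattered"` instead draws
#' the same number of signal features uniformly at random, a no-advantage
#' regime for phylogeny-aware weighting.
#'
#' @param n_samples,n_features dimensions (>= 10 each).
#' @param task `"classification"` or `"regression"`.
#' @param signal_fraction target share of features carrying signal
#'   (default 0.25).
#' @param effect_size log-odds (classification) or slope (regression) per
#'   standard deviation of the signal summary; default 5, a strong,
#'   recoverable signal.
#' @param zero_prob zero-inflation probability in `[0, 1)`; default 0.7,
#'   typical of sparse 16S feature tables.
#' @param meanlog,sdlog log-normal abundance parameters (defaults 0 and 2:
#'   heavy right skew / overdispersion).
#' @param noise_sd regression noise standard deviation (default 1).
#' @param lib_size_range per-sample library size range (default 5,000 to
#'   50,000 reads).
#' @param branch_rate exponential branch-length rate for the tree.
#' @param signal_mode `"clade"` (default) or `"scattered"`.
#' @param seed optional integer seed; the full (tree, table, outcome)
#'   triple is bit-reproducible given the seed.
#' @return a list of class `pirf_sim`: `tree`, `counts` (samples x
#'   features), `y`, `signal_features`, `signal_is_clade`, and `config`.
#' @export
simulate_dataset <- function(n_samples = 120L, n_features = 40L,
                             task = c("classification", "regression"),
                             signal_fraction = 0.25, effect_size = 5,
                             zero_prob = 0.7, meanlog = 0, sdlog = 2,
                             noise_sd = 1, lib_size_range = c(5000, 50000),
                             branch_rate = 1,
                             signal_mode = c("clade", "scattered"),
                             seed = NULL) {
  task <- match.arg(task)
  signal_mode <- match.arg(signal_mode)
  if (n_samples < 10L) stop_validation("'n_samples' must be >= 10")
  if (n_features < 10L) stop_validation("'n_features' must be >= 10")
  if (zero_prob < 0 || zero_prob >= 1)
    stop_validation("'zero_prob' must be in [0, 1)")
  if (sdlog <= 0) stop_validation("'sdlog' must be > 0")

  with_rng_seed(seed, {
    tree <- simulate_tree(n_features, branch_rate = branch_rate)
    n <- as.integer(n_samples)
    p <- as.integer(n_features)

    target <- signal_fraction * p
    if (signal_mode == "clade") {
      clades <- ape::prop.part(tree)
      sizes <- lengths(clades)
      keep <- sizes < p # exclude the root clade (all leaves)
      if (!any(keep))
        stop_validation("tree has no proper clade; cannot place a signal clade")
      cl_idx <- which(keep)
      best <- cl_idx[which.min(abs(sizes[keep] - target))]
      if (abs(sizes[best] - target) > 0.5 * target)
        stop_validation("no clade within 50% of the target signal fraction ",
                        signal_fraction, "; closest clade has ", sizes[best],
                        " of ", p, " leaves -- try a different fraction")
      signal <- tree$tip.label[clades[[best]]]
    } else {
      signal <- sample(tree$tip.label, max(2L, round(target)))
    }

    # zero-inflated log-normal relative profiles
    ab <- matrix(stats::rlnorm(n * p, meanlog = meanlog, sdlog = sdlog), n, p)
    mask <- matrix(stats::rbinom(n * p, 1L, zero_prob) == 1L, n, p)
    ab[mask] <- 0
    empty <- rowSums(ab) == 0
    for (i in which(empty)) # vanishingly rare; keep every sample usable
      ab[i, sample.int(p, 1L)] <- stats::rlnorm(1L, meanlog, sdlog)
    rel <- ab / rowSums(ab)

    lib <- round(stats::runif(n, lib_size_range[1], lib_size_range[2]))
    counts <- round(rel * lib)
    dimnames(counts) <- list(paste0("s", seq_len(n)), tree$tip.label)

    sig_cols <- match(signal, tree$tip.label)
    s <- rowSums(rel[, sig_cols, drop = FALSE])
    z <- as.numeric(scale(s))
    y <- if (task == "classification") {
      pr <- stats::plogis(effect_size * z)
      factor(ifelse(stats::rbinom(n, 1L, pr) == 1L, "pos", "neg"),
             levels = c("neg", "pos"))
    } else {
      effect_size * z + stats::rnorm(n, 0, noise_sd)
    }

    structure(list(tree = tree,
                   counts = counts,
                   y = y,
                   signal_features = signal,
                   signal_is_clade = signal_mode == "clade",
                   config = list(n_samples = n, n_features = p, task = task,
                                 signal_fraction = signal_fraction,
                                 effect_size = effect_size,
                                 zero_prob = zero_prob, meanlog = meanlog,
                                 sdlog = sdlog, noise_sd = noise_sd,
                                 lib_size_range = lib_size_range,
                                 branch_rate = branch_rate,
                                 signal_mode = signal_mode, seed = seed)),
              class = "pirf_sim")
  })
}

#' @export
print.pirf_sim <- function(x, ...) {
  cat("Synthetic microbiome dataset: ", nrow(x$counts), " samples x ",
      ncol(x$counts), " features (", x$config$task, ")\n",
      "  signal: ", length(x$signal_features), " feature(s), ",
      if (x$signal_is_clade) "one clade" else "scattered", "\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes `tree.nwk` (Newick), `table.tsv` (samples x features, first
#' column `sample_id`), and `meta.tsv` (columns `sample_id`, `outcome`),
#' directly consumable by the command-line `fit`/`cv` subcommands.
#'
#' @param sim a `pirf_sim` object.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  tab <- data.frame(sample_id = rownames(sim$counts), sim$counts,
                    check.names = FALSE)
  utils::write.table(tab, file.path(dir, "table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = rownames(sim$counts),
                     outcome = as.character(sim$y))
  utils::write.table(meta, file.path(dir, "meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
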