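# Synthetic corpora and drug-target datasets with a planted, recoverable
# interaction signal.

#' Default SMILES-like and protein alphabets
#'
#' A compact chemical alphabet (element symbols, bonds, branches, ring
#' closures) for SMILES-like strings, and the 20 standard amino-acid
#' letters.
#' @name alphabets
#' @export
smiles_alphabet <- function() {
  c("C", "N", "O", "S", "P", "F", "c", "n", "o", "s",
    "=", "#", "(", ")", "1", "2")
}

#' @rdname alphabets
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Generate a random sequence corpus
#'
#' `n` i.i.d. strings with characters drawn uniformly from `alphabet` and
#' lengths drawn uniformly from `len_range`; reproducible from `seed`.
#'
#' @param n number of strings (0 gives an empty character vector).
#' @param alphabet character vector of single characters.
#' @param len_range integer length-2 vector `(min, max)`.
#' @param seed integer seed.
#' @return character vector of length `n`.
#' @export
generate_corpus <- function(n, alphabet = aa_alphabet(), len_range = c(50L, 200L),
                            seed = 1L) {
  if (length(alphabet) == 0) input_error("generate_corpus: empty alphabet")
  if (n == 0) return(character(0))
  with_seed(seed, {
    lens <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
    vapply(lens, function(L)
      paste(sample(alphabet, L, replace = TRUE), collapse = ""), character(1))
  })
}

#' Synthetic-dataset configuration
#'
#' Defaults emulate a desk-scale, KIBA-like dataset: a moderately dense
#' interaction grid (density 0.25), short SMILES-like drugs, protein-like
#' targets, three planted motif interactions, and mild observation noise on
#' a pKd-like affinity scale (baseline 5, per-motif effects close to 1).
#'
#' @param n_drugs,n_targets grid dimensions.
#' @param density fraction of the grid observed, in (0, 1].
#' @param drug_len_range,target_len_range string length intervals.
#' @param n_motifs number of planted drug-motif x target-motif interactions.
#' @param motif_prob probability a given motif is inserted into a given
#'   entity.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param baseline affinity baseline.
#' @param degree_bias `"uniform"` pair sampling, or `"power"` for a
#'   power-law drug-degree stress test.
#' @param seed integer seed.
#' @return a `mildta_synth_config` list.
#' @export
synth_config <- function(n_drugs = 50L, n_targets = 30L, density = 0.25,
                         drug_len_range = c(20L, 40L),
                         target_len_range = c(60L, 120L),
                         n_motifs = 3L, motif_prob = 0.5, noise_sd = 0.2,
                         baseline = 5, degree_bias = c("uniform", "power"),
                         seed = 1L) {
  if (density <= 0 || density > 1) input_error("synth_config: density must be in (0, 1]")
  if (density * n_drugs * n_targets < 1)
    input_error("synth_config: density infeasible for grid size")
  cfg <- list(n_drugs = as.integer(n_drugs), n_targets = as.integer(n_targets),
              density = density,
              drug_len_range = as.integer(drug_len_range),
              target_len_range = as.integer(target_len_range),
              n_motifs = as.integer(n_motifs), motif_prob = motif_prob,
              noise_sd = noise_sd, baseline = baseline,
              degree_bias = match.arg(degree_bias), seed = as.integer(seed))
  class(cfg) <- "mildta_synth_config"
  cfg
}

insert_motif <- function(s, motif) {
  pos <- sample.int(nchar(s) + 1L, 1L) - 1L
  paste0(substr(s, 1, pos), motif, substr(s, pos + 1, nchar(s)))
}

#' Generate a synthetic drug-target affinity dataset with a planted signal
#'
#' Random SMILES-like drugs and protein-like targets carry randomly inserted
#' motif substrings. The affinity of a pair is
#' `baseline + sum_k a_k * I(motif_k in drug) * I(motif'_k in target)`
#' plus Gaussian noise: the signal is multiplicative in drug and target
#' motif indicators, so neither a drug-only nor a target-only model can fit
#' it, which specifically exercises the interaction (public) instances.
#' Observed pairs are sampled to match the configured density.
#'
#' @param cfg a [synth_config()].
#' @return list with `dataset` (a `mildta_dataset`) and `ground_truth`
#'   (drug motifs, target motifs, effects `a`, baseline, and the indicator
#'   matrices actually realised in the strings).
#' @export
generate_dt_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "mildta_synth_config"))
  with_seed(cfg$seed, {
    d_alpha <- smiles_alphabet(); t_alpha <- aa_alphabet()
    drugs <- vapply(sample(seq(cfg$drug_len_range[1], cfg$drug_len_range[2]),
                           cfg$n_drugs, replace = TRUE),
                    function(L) paste(sample(d_alpha, L, replace = TRUE), collapse = ""),
                    character(1))
    targets <- vapply(sample(seq(cfg$target_len_range[1], cfg$target_len_range[2]),
                             cfg$n_targets, replace = TRUE),
                      function(L) paste(sample(t_alpha, L, replace = TRUE), collapse = ""),
                      character(1))
    motifs_d <- vapply(seq_len(cfg$n_motifs), function(k)
      paste(sample(d_alpha, 4L, replace = TRUE), collapse = ""), character(1))
    motifs_t <- vapply(seq_len(cfg$n_motifs), function(k)
      paste(sample(t_alpha, 5L, replace = TRUE), collapse = ""), character(1))
    a <- stats::runif(cfg$n_motifs, 0.8, 1.6)

    for (k in seq_len(cfg$n_motifs)) {
      ins_d <- stats::runif(cfg$n_drugs) < cfg$motif_prob
      drugs[ins_d] <- vapply(drugs[ins_d], insert_motif, character(1),
                             motif = motifs_d[k])
      ins_t <- stats::runif(cfg$n_targets) < cfg$motif_prob
      targets[ins_t] <- vapply(targets[ins_t], insert_motif, character(1),
                               motif = motifs_t[k])
    }
    # Indicators from the realised strings (chance hits count too, so the
    # label function is an exact function of the sequences).
    ind_d <- vapply(motifs_d, function(m) grepl(m, drugs, fixed = TRUE),
                    logical(cfg$n_drugs))
    ind_t <- vapply(motifs_t, function(m) grepl(m, targets, fixed = TRUE),
                    logical(cfg$n_targets))
    ind_d <- matrix(ind_d, nrow = cfg$n_drugs)
    ind_t <- matrix(ind_t, nrow = cfg$n_targets)

    d_ids <- sprintf("D%03d", seq_len(cfg$n_drugs))
    t_ids <- sprintf("T%03d", seq_len(cfg$n_targets))
    n_cells <- cfg$n_drugs * cfg$n_targets
    n_obs <- max(1L, round(cfg$density * n_cells))
    cells <- if (cfg$degree_bias == "uniform") {
      sample.int(n_cells, n_obs)
    } else {
      w <- rep(1 / seq_len(cfg$n_drugs)^0.8, times = cfg$n_targets)
      sample.int(n_cells, n_obs, prob = w)
    }
    di <- ((cells - 1L) %% cfg$n_drugs) + 1L
    ti <- ((cells - 1L) %/% cfg$n_drugs) + 1L
    signal <- cfg$baseline +
      rowSums(ind_d[di, , drop = FALSE] * ind_t[ti, , drop = FALSE] *
                matrix(a, length(di), cfg$n_motifs, byrow = TRUE))
    y <- signal + if (cfg$noise_sd > 0) stats::rnorm(n_obs, 0, cfg$noise_sd) else 0

    ds <- dt_dataset(drugs = stats::setNames(drugs, d_ids),
                     targets = stats::setNames(targets, t_ids),
                     pairs = data.frame(drug_id = d_ids[di], target_id = t_ids[ti],
                                        affinity = y, stringsAsFactors = FALSE))
    list(dataset = ds,
         ground_truth = list(motifs_d = motifs_d, motifs_t = motifs_t, a = a,
                             baseline = cfg$baseline,
                             ind_d = ind_d, ind_t = ind_t))
  })
}
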