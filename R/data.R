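# Dataset loading, statistics, and random / blind splitting.

#' Construct a drug-target affinity dataset
#'
#' @param drugs named character vector: drug id -> SMILES.
#' @param targets named character vector: target id -> amino-acid sequence.
#' @param pairs data.frame with columns `drug_id`, `target_id`, `affinity`.
#' @return a `mildta_dataset`: list with `drugs`, `targets`, `pairs`.
#' @export
dt_dataset <- function(drugs, targets, pairs) {
  pairs$drug_id <- as.character(pairs$drug_id)
  pairs$target_id <- as.character(pairs$target_id)
  pairs$affinity <- as.numeric(pairs$affinity)
  missing_d <- setdiff(pairs$drug_id, names(drugs))
  if (length(missing_d))
    input_error(paste0("dt_dataset: pairs reference unknown drug ids: ",
                       paste(utils::head(missing_d, 5), collapse = ", ")))
  missing_t <- setdiff(pairs$target_id, names(targets))
  if (length(missing_t))
    input_error(paste0("dt_dataset: pairs reference unknown target ids: ",
                       paste(utils::head(missing_t, 5), collapse = ", ")))
  key <- paste(pairs$drug_id, pairs$target_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    input_error(paste0("dt_dataset: duplicate (drug, target) pairs at rows: ",
                       paste(utils::head(dup, 5), collapse = ", ")))
  }
  if (anyNA(pairs$affinity)) {
    bad <- which(is.na(pairs$affinity))
    input_error(paste0("dt_dataset: non-numeric affinity at rows: ",
                       paste(utils::head(bad, 5), collapse = ", ")))
  }
  out <- list(drugs = drugs, targets = targets,
              pairs = pairs[, c("drug_id", "target_id", "affinity")])
  rownames(out$pairs) <- NULL
  class(out) <- "mildta_dataset"
  out
}

#' @export
print.mildta_dataset <- function(x, ...) {
  s <- dataset_stats(x)
  cat(sprintf("Drug-target affinity dataset: %d drugs x %d targets, %d pairs (sparsity %.4g)\n",
              s$n_drugs, s$n_targets, s$n_pairs, s$sparsity))
  invisible(x)
}

#' Load a drug-target affinity dataset
#'
#' Two plain-text dialects are supported:
#' \describe{
#'   \item{`pairs-table`}{a CSV or TSV file (delimiter sniffed from the
#'     extension) with header columns `drug_id`, `smiles`, `target_id`,
#'     `sequence`, `affinity`, one observed pair per row.}
#'   \item{`deepdta-folder`}{a directory with `ligands.tsv` (columns
#'     `drug_id`, `smiles`), `proteins.tsv` (columns `target_id`,
#'     `sequence`) and `affinities.tsv`, a drug x target matrix whose first
#'     column holds drug ids, whose header holds target ids, and whose
#'     empty/NA cells mark unobserved pairs.}
#' }
#'
#' @param path file (pairs-table) or directory (deepdta-folder).
#' @param format `"pairs-table"` or `"deepdta-folder"`.
#' @return a `mildta_dataset`.
#' @export
load_dataset <- function(path, format = c("pairs-table", "deepdta-folder")) {
  format <- match.arg(format)
  if (format == "pairs-table") {
    if (!file.exists(path)) input_error(paste0("load_dataset: no such file: ", path))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            colClasses = "character", quote = "",
                            comment.char = "")
    need <- c("drug_id", "smiles", "target_id", "sequence", "affinity")
    if (!all(need %in% names(df)))
      input_error(paste0("load_dataset: missing columns: ",
                         paste(setdiff(need, names(df)), collapse = ", ")))
    if (nrow(df) == 0) input_error("load_dataset: empty dataset")
    aff <- suppressWarnings(as.numeric(df$affinity))
    if (anyNA(aff)) {
      bad <- which(is.na(aff)) + 1L  # +1 for header line
      input_error(paste0("load_dataset: unparseable affinity at line(s): ",
                         paste(utils::head(bad, 5), collapse = ", ")))
    }
    drugs <- tapply(df$smiles, df$drug_id, `[`, 1)
    targets <- tapply(df$sequence, df$target_id, `[`, 1)
    dt_dataset(drugs = stats::setNames(as.character(drugs), names(drugs)),
               targets = stats::setNames(as.character(targets), names(targets)),
               pairs = data.frame(drug_id = df$drug_id, target_id = df$target_id,
                                  affinity = aff, stringsAsFactors = FALSE))
  } else {
    if (!dir.exists(path)) input_error(paste0("load_dataset: no such directory: ", path))
    lig <- utils::read.table(file.path(path, "ligands.tsv"), header = TRUE,
                             sep = "\t", colClasses = "character")
    pro <- utils::read.table(file.path(path, "proteins.tsv"), header = TRUE,
                             sep = "\t", colClasses = "character")
    aff <- utils::read.table(file.path(path, "affinities.tsv"), header = TRUE,
                             sep = "\t", row.names = 1, check.names = FALSE)
    aff <- as.matrix(aff)
    obs <- which(!is.na(aff), arr.ind = TRUE)
    if (nrow(obs) == 0) input_error("load_dataset: empty dataset (no observed cells)")
    pairs <- data.frame(drug_id = rownames(aff)[obs[, 1]],
                        target_id = colnames(aff)[obs[, 2]],
                        affinity = as.numeric(aff[obs]),
                        stringsAsFactors = FALSE)
    dt_dataset(drugs = stats::setNames(lig$smiles, lig$drug_id),
               targets = stats::setNames(pro$sequence, pro$target_id),
               pairs = pairs)
  }
}

#' Dataset summary statistics
#'
#' Counts of targets, drugs and observed pairs, and the sparsity
#' `n_pairs / (n_targets * n_drugs)` of the interaction matrix, reported raw
#' and rounded.
#'
#' @param ds a `mildta_dataset`.
#' @param round_digits digits for the rounded sparsity (default 4).
#' @return list with `n_targets`, `n_drugs`, `n_pairs`, `sparsity`,
#'   `sparsity_rounded`.
#' @export
dataset_stats <- function(ds, round_digits = 4L) {
  stopifnot(inherits(ds, "mildta_dataset"))
  n_t <- length(ds$targets); n_d <- length(ds$drugs); n_p <- nrow(ds$pairs)
  sp <- n_p / (n_t * n_d)
  list(n_targets = n_t, n_drugs = n_d, n_pairs = n_p,
       sparsity = sp, sparsity_rounded = round(sp, round_digits))
}

new_split <- function(strategy, train, val, test, seed, ds, discarded = integer(0)) {
  out <- list(strategy = strategy, train = train, val = val, test = test,
              discarded = discarded, seed = seed)
  out$overlap <- overlap_report(out, ds)
  class(out) <- "mildta_split"
  out
}

#' Assemble a split from explicit pair-index lists
#'
#' For custom protocols (e.g. capacity checks that train on every pair and
#' monitor a subset). No disjointness is enforced beyond basic validity.
#'
#' @param ds a `mildta_dataset`.
#' @param train,val,test integer pair indices into `ds$pairs`.
#' @return a `mildta_split` with strategy `"manual"`.
#' @export
manual_split <- function(ds, train, val, test = integer(0)) {
  n <- nrow(ds$pairs)
  idx <- c(train, val, test)
  if (length(idx) == 0 || any(idx < 1 | idx > n))
    input_error("manual_split: pair indices out of range")
  new_split("manual", train = as.integer(train), val = as.integer(val),
            test = as.integer(test), seed = NA_integer_, ds = ds)
}

#' Random pair-level cross-validation split
#'
#' Shuffles all observed pairs into `n_folds` balanced folds, designates one
#' fold as the test set, and splits the remaining pairs 80/20 into training
#' and validation sets. Pair-level splitting deliberately allows drugs and
#' targets to be shared across partitions (the standard, leaky random
#' setting).
#'
#' @param ds a `mildta_dataset`.
#' @param n_folds number of folds (default 5).
#' @param test_fold which fold is the test set (1-based).
#' @param seed integer seed; the split is a pure function of it.
#' @return a `mildta_split` with integer pair indices in `train`, `val`,
#'   `test` and an entity `overlap` report.
#' @export
random_split <- function(ds, n_folds = 5L, test_fold = 1L, seed = 1L) {
  stopifnot(inherits(ds, "mildta_dataset"))
  if (n_folds < 2) input_error("random_split: n_folds must be >= 2")
  if (test_fold < 1 || test_fold > n_folds)
    input_error("random_split: test_fold out of range")
  n <- nrow(ds$pairs)
  if (n < n_folds) input_error("random_split: fewer pairs than folds")
  with_seed(seed, {
    perm <- sample.int(n)
    fold <- rep_len(seq_len(n_folds), n)[order(perm)]  # balanced, shuffled
    test <- which(fold == test_fold)
    rest <- perm[!(perm %in% test)]                    # shuffled order retained
    n_train <- floor(0.8 * length(rest))
    new_split("random", train = sort(rest[seq_len(n_train)]),
              val = sort(rest[-seq_len(n_train)]),
              test = sort(test), seed = seed, ds = ds)
  })
}

#' Blind (cold) split with unseen drugs and targets
#'
#' Drugs and targets are independently partitioned 0.8/0.2 into
#' training-validation and test entity sets. A pair is a test pair only if
#' both its drug and its target are test entities; it is a
#' training-validation pair only if both are training-validation entities.
#' Mixed pairs would leak an entity across the boundary and are discarded
#' (their count is reported). Training-validation pairs are then split
#' 0.75/0.25 into training and validation.
#'
#' @param ds a `mildta_dataset`.
#' @param entity_test_frac fraction of drugs and of targets held out
#'   (default 0.2).
#' @param train_frac_of_trainval fraction of the retained pairs used for
#'   training (default 0.75).
#' @param seed integer seed.
#' @return a `mildta_split`; its `overlap` report has zero shared drugs and
#'   zero shared targets between train and test by construction.
#' @export
blind_split <- function(ds, entity_test_frac = 0.2, train_frac_of_trainval = 0.75,
                        seed = 1L) {
  stopifnot(inherits(ds, "mildta_dataset"))
  d_ids <- names(ds$drugs); t_ids <- names(ds$targets)
  if (length(d_ids) < 2 || length(t_ids) < 2)
    input_error("blind_split: need at least 2 drugs and 2 targets")
  with_seed(seed, {
    d_test <- sample(d_ids, max(1L, round(entity_test_frac * length(d_ids))))
    t_test <- sample(t_ids, max(1L, round(entity_test_frac * length(t_ids))))
    in_d <- ds$pairs$drug_id %in% d_test
    in_t <- ds$pairs$target_id %in% t_test
    test <- which(in_d & in_t)
    trainval <- which(!in_d & !in_t)
    discarded <- which(xor(in_d, in_t))
    if (length(test) == 0 || length(trainval) == 0)
      input_error("blind_split: a partition has zero usable pairs; try another seed")
    tv <- sample(trainval)
    n_train <- floor(train_frac_of_trainval * length(tv))
    sp <- new_split("blind", train = sort(tv[seq_len(n_train)]),
                    val = sort(tv[-seq_len(n_train)]),
                    test = sort(test), seed = seed, ds = ds,
                    discarded = discarded)
    message(sprintf("blind_split: kept %d pairs (train %d / val %d / test %d), discarded %d mixed pairs",
                    length(sp$train) + length(sp$val) + length(sp$test),
                    length(sp$train), length(sp$val), length(sp$test),
                    length(discarded)))
    sp
  })
}

#' Entity-overlap report between the train and test partitions
#'
#' Counts the drugs and targets that appear in pairs of both the training
#' and the test partitions (blind splits yield zero for both), along with
#' per-partition pair and entity counts.
#'
#' @param split a `mildta_split`.
#' @param ds the dataset it indexes.
#' @return list with `shared_drugs`, `shared_targets` and a `partitions`
#'   data.frame of per-partition counts.
#' @export
overlap_report <- function(split, ds) {
  ent <- function(idx) list(d = unique(ds$pairs$drug_id[idx]),
                            t = unique(ds$pairs$target_id[idx]))
  tr <- ent(split$train); va <- ent(split$val); te <- ent(split$test)
  list(shared_drugs = length(intersect(tr$d, te$d)),
       shared_targets = length(intersect(tr$t, te$t)),
       partitions = data.frame(
         partition = c("train", "val", "test"),
         n_pairs = c(length(split$train), length(split$val), length(split$test)),
         n_drugs = c(length(tr$d), length(va$d), length(te$d)),
         n_targets = c(length(tr$t), length(va$t), length(te$t))))
}

#' @export
print.mildta_split <- function(x, ...) {
  cat(sprintf("%s split (seed %d): train %d / val %d / test %d pairs",
              x$strategy, x$seed, length(x$train), length(x$val), length(x$test)))
  if (length(x$discarded)) cat(sprintf(" (+%d discarded)", length(x$discarded)))
  cat(sprintf("\n  shared drugs train/test: %d, shared targets: %d\n",
              x$overlap$shared_drugs, x$overlap$shared_targets))
  invisible(x)
}
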