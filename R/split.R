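# Age-stratified under-sampled train/test splits and the internal
# train/validation refinement.

#' Age-stratified under-sampled train/test split
#'
#' Bins the cohort into half-year age bins (bins below `collapse_below`
#' are merged into one, reflecting the thin lower tail), targets a
#' training cohort of `floor(n * train_frac)` and samples it with equal
#' per-bin quotas. When a bin holds fewer subjects than its quota all its
#' members are taken and the deficit is redistributed round-robin over
#' bins that still have members, so the training age histogram comes out
#' as flat as the data allow. The remainder is the test cohort.
#'
#' @param subject_id Character vector of subject ids.
#' @param ages Numeric ages, same length.
#' @param train_frac Training share of the cohort (3:1 split = 0.75).
#' @param bin_width Bin width in years.
#' @param collapse_below Ages below this bound form one merged bin.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return Tibble `subject_id`, `age`, `bin`, `partition`
#'   (`"train"`/`"test"`), with attributes `bin_edges`, `bin_counts`
#'   (sampled per bin), and `seed`.
#' @export
stratified_undersample <- function(subject_id, ages, train_frac = 0.75,
                                   bin_width = 0.5, collapse_below = 9,
                                   seed = 1L) {
  n <- length(ages)
  stopifnot(length(subject_id) == n)
  if (n == 0) stop("empty cohort", call. = FALSE)
  lo <- min(ages)
  hi <- max(ages)
  eps <- 1e-9
  # half-year bin boundaries from the collapse bound upward; everything
  # below the bound falls into one merged bin
  uppers <- if (hi >= collapse_below) {
    seq(collapse_below, hi + bin_width, by = bin_width)
  } else numeric(0)
  edges <- sort(unique(c(lo - eps, uppers[uppers > lo & uppers <= hi],
                         hi + eps)))
  bin <- cut(ages, breaks = edges, right = FALSE, include.lowest = TRUE)
  bins <- levels(droplevels(bin))
  bin <- as.character(droplevels(bin))
  if (length(bins) == 0) stop("no non-empty age bins", call. = FALSE)

  n_train <- floor(n * train_frac)
  counts <- table(factor(bin, levels = bins))
  quota <- pmin(as.integer(counts), n_train %/% length(bins))
  deficit <- n_train - sum(quota)
  while (deficit > 0) {
    progressed <- FALSE
    for (b in seq_along(bins)) {
      if (deficit == 0) break
      if (quota[b] < counts[b]) {
        quota[b] <- quota[b] + 1
        deficit <- deficit - 1
        progressed <- TRUE
      }
    }
    if (!progressed) break   # every bin exhausted (n_train == n)
  }

  train_ids <- withr::with_seed(seed, {
    unlist(lapply(seq_along(bins), function(b) {
      members <- subject_id[bin == bins[b]]
      if (quota[b] >= length(members)) members
      else sample(members, quota[b])
    }))
  })
  out <- tibble::tibble(
    subject_id = subject_id,
    age = ages,
    bin = bin,
    partition = ifelse(subject_id %in% train_ids, "train", "test")
  )
  attr(out, "bin_edges") <- edges
  attr(out, "bin_counts") <- stats::setNames(as.integer(quota), bins)
  attr(out, "seed") <- seed
  out
}

#' Refine the training cohort into internal training / validation
#'
#' Simple random subdivision of the training cohort at `frac` (5:1 split
#' = 5/6), used to select the learning algorithm and kernel without
#' touching the held-out test cohort.
#'
#' @param split Tibble from [stratified_undersample()] (or any tibble
#'   with `subject_id` and `partition` columns).
#' @param frac Internal-training share of the training cohort.
#' @param seed Integer seed.
#' @return The split tibble with `partition` refined to
#'   `"internal_train"` / `"internal_validation"` / `"test"`.
#' @export
internal_split <- function(split, frac = 5 / 6, seed = 1L) {
  train_ids <- split$subject_id[split$partition == "train"]
  n_train <- length(train_ids)
  if (n_train < 6) stop("training cohort too small to subdivide (< 6)",
                        call. = FALSE)
  n_int <- floor(frac * n_train)
  int_ids <- withr::with_seed(seed, sample(train_ids, n_int))
  out <- split
  out$partition[out$subject_id %in% int_ids] <- "internal_train"
  out$partition[out$partition == "train"] <- "internal_validation"
  attr(out, "internal_seed") <- seed
  out
}

#' Partition helper
#'
#' @param split A split tibble.
#' @param which Partition label(s); `"train"` means the full training
#'   cohort (internal training plus validation).
#' @return Character vector of subject ids.
#' @export
split_ids <- function(split, which) {
  if (identical(which, "train")) {
    which <- c("train", "internal_train", "internal_validation")
  }
  split$subject_id[split$partition %in% which]
}
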