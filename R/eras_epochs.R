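#' The eras/epochs balanced training scheduler
#'
#' Lesion segmentation datasets are dominated by healthy slices. The
#' eras/epochs schema redefines an *epoch* as the network having seen all
#' minority-class (lesion) samples plus an equally sized randomly chosen
#' block — a *chunk* — of majority-class (healthy) samples; an *era* is one
#' pass over all chunks, i.e. over every majority sample. Chunks are
#' re-drawn every era, so later eras pair the minority set with fresh
#' majority contexts: class balancing and augmentation without fabricating
#' samples.
#'
#' `plan_era()` shuffles the majority indices with a generator seeded from
#' `(seed, era_index)` and partitions them into `ceiling(M/m)` chunks of
#' exactly `m` indices; a short final chunk is padded by resampling (without
#' replacement) indices already assigned to earlier chunks, so every epoch
#' stays exactly balanced at `2m` samples.
#'
#' @param majority_ids,minority_ids disjoint index vectors (sizes `M >= m >= 1`).
#' @param era_index 1-based era counter.
#' @param seed integer; together with `era_index` it fixes the plan.
#' @return a `chunk_plan`: `minority_ids`, `chunks` (list of length
#'   `ceiling(M/m)`, each of length `m`), `era_index`, `seed`.
#' @export
plan_era <- function(majority_ids, minority_ids, era_index = 1L, seed = 0L) {
  M <- length(majority_ids); m <- length(minority_ids)
  if (m < 1L || M < 1L)
    stop("both classes must be non-empty", call. = FALSE)
  if (m > M)
    stop("minority class larger than majority class: swap the roles",
         call. = FALSE)
  n_chunks <- ceiling(M / m)
  era_seed <- (as.double(seed) + 1000003 * as.double(era_index)) %% 2147483647
  perm <- with_seed(as.integer(era_seed), {
    p <- majority_ids[sample.int(M)]
    deficit <- n_chunks * m - M
    pad <- if (deficit > 0) {
      earlier <- p[seq_len(M - (M %% m))]
      earlier[sample.int(length(earlier), deficit)]
    }
    c(p, pad)
  })
  chunks <- split(perm, rep(seq_len(n_chunks), each = m))
  names(chunks) <- NULL
  structure(list(minority_ids = minority_ids, chunks = chunks,
                 era_index = as.integer(era_index), seed = as.integer(seed)),
            class = "chunk_plan")
}

#' @export
print.chunk_plan <- function(x, ...) {
  cat(sprintf("<chunk_plan era %d> %d chunks of %d majority + %d minority samples each\n",
              x$era_index, length(x$chunks), length(x$chunks[[1L]]),
              length(x$minority_ids)))
  invisible(x)
}

#' Batches of one balanced epoch
#'
#' The multiset `chunk[epoch_index] U minority_ids` (exactly `2m` samples,
#' 50/50 by class) is shuffled with a seeded generator and cut into
#' `ceiling(2m / batch_size)` batches; batches never cross chunks.
#'
#' @param plan a [plan_era()] result.
#' @param epoch_index 1-based chunk/epoch index within the era.
#' @param batch_size samples per batch (>= 1).
#' @param seed integer.
#' @return an `epoch_batch_stream`: list `batches` of index vectors, plus
#'   `batch_size` and `epoch_index`.
#' @export
epoch_batches <- function(plan, epoch_index, batch_size, seed = 0L) {
  stopifnot(inherits(plan, "chunk_plan"))
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (epoch_index < 1L || epoch_index > length(plan$chunks))
    stop("epoch_index out of range for this era's ", length(plan$chunks),
         " chunks", call. = FALSE)
  pool <- c(plan$chunks[[epoch_index]], plan$minority_ids)
  es <- (as.double(seed) + 7907 * as.double(plan$era_index) +
           104729 * as.double(epoch_index)) %% 2147483647
  pool <- with_seed(as.integer(es), pool[sample.int(length(pool))])
  n_batches <- ceiling(length(pool) / batch_size)
  batches <- split(pool, rep(seq_len(n_batches), each = batch_size,
                             length.out = length(pool)))
  names(batches) <- NULL
  structure(list(batches = batches, batch_size = as.integer(batch_size),
                 epoch_index = as.integer(epoch_index)),
            class = "epoch_batch_stream")
}

#' Era bookkeeping closed forms
#'
#' @param n_majority,n_minority class sizes `M`, `m` (>= 1, `m <= M`).
#' @return list with `chunks_per_era = ceiling(M/m)` and
#'   `samples_per_era = 2 m ceiling(M/m)` (padded-chunk convention).
#' @export
era_accounting <- function(n_majority, n_minority) {
  stopifnot(n_majority >= 1, n_minority >= 1, n_minority <= n_majority)
  ch <- ceiling(n_majority / n_minority)
  list(chunks_per_era = as.integer(ch),
       samples_per_era = as.integer(2 * n_minority * ch))
}
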