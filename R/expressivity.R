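#' @title Context-nested facial expressivity measures
#' @description
#' Converts MaqFACS event streams into four expressivity measures, each
#' computed per context and then averaged so every context carries equal
#' weight (observation time of contexts varies across individuals, and
#' context-specific behaviour should not bias the final scores):
#' \itemize{
#'   \item AU rate: facial movements per second of true observation time.
#'   \item AU duration: percentage of true observation time with an AU
#'     active (sum of AU durations; overlapping AUs can push this past
#'     100%).
#'   \item AU diversity: the exponentiated Shannon entropy of AU usage —
#'     the effective number of AUs used evenly, between 1 and the
#'     repertoire size.
#'   \item AU proportion: each AU's share of all facial movements, pooled
#'     across contexts.
#' }
#' True observation time is footage minus out-of-sight (`AUX`) time.
#' `AU43` (eyes closed) never counts; during feeding (`AD50a`) intervals,
#' mastication-related codes (default AU25, AU26) are dropped while other
#' AUs count as normal.
#' @name expressivity
NULL

# --- interval utilities (intervals are [onset, offset) on one video) ------

.merge_intervals <- function(on, off) {
  if (!length(on)) return(cbind(on = numeric(0), off = numeric(0)))
  o <- order(on)
  on <- on[o]; off <- off[o]
  m_on <- on[1]; m_off <- off[1]
  res_on <- numeric(0); res_off <- numeric(0)
  for (i in seq_along(on)[-1]) {
    if (on[i] <= m_off) m_off <- max(m_off, off[i])
    else { res_on <- c(res_on, m_on); res_off <- c(res_off, m_off)
           m_on <- on[i]; m_off <- off[i] }
  }
  cbind(on = c(res_on, m_on), off = c(res_off, m_off))
}

# total overlap of each [on, off) with a merged interval set; vectorized
# over events
.overlap_len <- function(on, off, merged) {
  if (!nrow(merged) || !length(on)) return(rep(0, length(on)))
  tot <- rep(0, length(on))
  for (i in seq_len(nrow(merged)))
    tot <- tot + pmax(0, pmin(off, merged[i, 2]) - pmax(on, merged[i, 1]))
  tot
}

.point_in <- function(x, merged) {
  if (!nrow(merged) || !length(x)) return(rep(FALSE, length(x)))
  inside <- rep(FALSE, length(x))
  for (i in seq_len(nrow(merged)))
    inside <- inside | (x >= merged[i, 1] & x < merged[i, 2])
  inside
}

# --- ledger ---------------------------------------------------------------

#' Build the per-context expressivity ledger
#'
#' For every subject and context: true observation time `t` (context
#' footage minus out-of-sight time), AU event count `f`, summed AU duration
#' `d` (and the union-of-intervals alternative `d_union`), and per-AU
#' counts. Events are assigned to the context active at their onset;
#' durations are truncated at out-of-sight boundaries; events entirely out
#' of sight are dropped, as are `AU43` and mastication-mask codes whose
#' onset falls in a feeding interval.
#'
#' @param au_events AU event table including `AUX`/`AD50a` rows.
#' @param context_timeline Context timeline table.
#' @param config A [run_config()] (mastication mask, context set).
#' @param union_durations Also compute the union-of-active-intervals
#'   duration variant (`d_union`); off by default, as only the summed
#'   variant enters the standard measures.
#' @return List of class `maqsoc_ledger`: `context` (data.frame
#'   `subject_id, context, t, f, d, d_union`) and `au_counts` (data.frame
#'   `subject_id, context, au_code, n`).
#' @export
build_ledger <- function(au_events, context_timeline,
                         config = run_config(),
                         union_durations = FALSE) {
  vocab <- maqfacs_vocabulary()$code
  subjects <- sort(unique(context_timeline$subject_id))
  contexts <- config$contexts
  tl_by_s <- split(context_timeline,
                   factor(context_timeline$subject_id, levels = subjects))
  ev_by_s <- split(au_events,
                   factor(au_events$subject_id, levels = subjects))
  ctx_rows <- list(); cnt_rows <- list()
  for (s in subjects) {
    tl_s <- tl_by_s[[s]]
    ev_s <- ev_by_s[[s]]
    videos <- unique(tl_s$video_id)
    # plain vectors: event tables are subset many times per video
    e_vid <- ev_s$video_id; e_code <- ev_s$au_code
    e_on <- ev_s$onset; e_off <- ev_s$offset; e_ctx <- ev_s$context
    tl_idx <- split(seq_len(nrow(tl_s)),
                    factor(tl_s$video_id, levels = videos))
    ev_idx <- split(seq_along(e_vid), factor(e_vid, levels = videos))
    t_c <- stats::setNames(rep(0, length(contexts)), contexts)
    # accumulated surviving events across videos
    a_ctx <- character(0); a_code <- character(0); a_dur <- numeric(0)
    union_pieces <- stats::setNames(vector("list", length(contexts)),
                                    contexts)
    for (v in videos) {
      ti <- tl_idx[[v]]
      ei <- ev_idx[[v]]
      is_aux <- e_code[ei] == "AUX"
      is_feed <- e_code[ei] == "AD50a"
      aux <- .merge_intervals(e_on[ei][is_aux], e_off[ei][is_aux])
      feed <- .merge_intervals(e_on[ei][is_feed], e_off[ei][is_feed])
      # context true observation time: footage minus out-of-sight overlap
      seg_len <- tl_s$offset[ti] - tl_s$onset[ti] -
        .overlap_len(tl_s$onset[ti], tl_s$offset[ti], aux)
      t_add <- tapply(seg_len, factor(tl_s$context[ti], levels = contexts),
                      sum)
      t_add[is.na(t_add)] <- 0
      t_c <- t_c + t_add
      ai <- ei[e_code[ei] %in% vocab]
      if (!length(ai)) next
      # feeding mask: mastication-related codes starting during AD50a
      drop_feed <- e_code[ai] %in% config$mastication_mask &
        .point_in(e_on[ai], feed)
      ai <- ai[!drop_feed]
      if (!length(ai)) next
      aux_ov <- .overlap_len(e_on[ai], e_off[ai], aux)
      dur <- e_off[ai] - e_on[ai] - aux_ov
      visible <- dur > 1e-12   # events entirely out of sight are dropped
      ai <- ai[visible]
      dur <- dur[visible]
      if (!length(ai)) next
      a_ctx <- c(a_ctx, e_ctx[ai])
      a_code <- c(a_code, e_code[ai])
      a_dur <- c(a_dur, dur)
      if (union_durations) {
        # pieces of each event with out-of-sight stretches cut out, for
        # the union-of-active-time duration variant
        for (i in seq_along(ai)) {
          pieces <- .interval_minus(e_on[ai[i]], e_off[ai[i]], aux)
          ctx <- e_ctx[ai[i]]
          union_pieces[[ctx]] <- rbind(union_pieces[[ctx]], pieces)
        }
      }
    }
    cf <- factor(a_ctx, levels = contexts)
    f_c <- as.numeric(table(cf))
    d_c <- tapply(a_dur, cf, sum)
    d_c[is.na(d_c)] <- 0
    counts <- table(cf, factor(a_code, levels = vocab))
    d_union <- if (union_durations) {
      vapply(contexts, function(ctx) {
        p <- union_pieces[[ctx]]
        if (is.null(p) || !nrow(p)) return(0)
        mg <- .merge_intervals(p[, 1], p[, 2])
        sum(mg[, 2] - mg[, 1])
      }, numeric(1))
    } else rep(NA_real_, length(contexts))
    ctx_rows[[s]] <- data.frame(
      subject_id = s, context = contexts,
      t = as.numeric(t_c), f = f_c, d = as.numeric(d_c),
      d_union = as.numeric(d_union), stringsAsFactors = FALSE)
    idx <- which(counts > 0, arr.ind = TRUE)
    if (nrow(idx))
      cnt_rows[[s]] <- data.frame(
        subject_id = s, context = rownames(counts)[idx[, 1]],
        au_code = colnames(counts)[idx[, 2]], n = as.numeric(counts[idx]),
        stringsAsFactors = FALSE)
  }
  structure(list(context = do.call(rbind, ctx_rows),
                 au_counts = do.call(rbind, cnt_rows),
                 contexts = config$contexts),
            class = "maqsoc_ledger")
}

# [on, off) minus a merged interval set -> matrix of remaining pieces
.interval_minus <- function(on, off, merged) {
  pieces <- cbind(on, off)
  if (!nrow(merged)) return(pieces)
  for (i in seq_len(nrow(merged))) {
    out <- NULL
    for (j in seq_len(nrow(pieces))) {
      a <- pieces[j, 1]; b <- pieces[j, 2]
      lo <- merged[i, 1]; hi <- merged[i, 2]
      if (hi <= a || lo >= b) { out <- rbind(out, c(a, b)); next }
      if (lo > a) out <- rbind(out, c(a, lo))
      if (hi < b) out <- rbind(out, c(hi, b))
    }
    pieces <- if (is.null(out)) cbind(numeric(0), numeric(0)) else out
    if (!nrow(pieces)) break
  }
  pieces
}

# --- per-context measures -------------------------------------------------

#' Per-context AU rate and duration
#'
#' Rate is events per second of true observation time; duration is the
#' summed AU time as a percentage of true observation time (may exceed
#' 100% when AUs overlap). Contexts with no observation time are excluded.
#'
#' @param ledger A [build_ledger()] result.
#' @param duration_method `"sum"` (the literal sum of AU durations,
#'   default) or `"union"` (union of active intervals, bounded by 100%).
#' @return Data.frame `subject_id, context, t, rate, duration_pct`.
#' @export
rate_duration_per_context <- function(ledger,
                                      duration_method = c("sum", "union")) {
  duration_method <- match.arg(duration_method)
  cx <- ledger$context[ledger$context$t > 0, ]
  d <- if (duration_method == "sum") cx$d else cx$d_union
  if (duration_method == "union" && anyNA(d))
    stop("ledger built without union durations; ",
         "rerun build_ledger(union_durations = TRUE)")
  data.frame(subject_id = cx$subject_id, context = cx$context, t = cx$t,
             rate = cx$f / cx$t, duration_pct = 100 * d / cx$t,
             stringsAsFactors = FALSE)
}

#' Per-context AU diversity (effective numbers)
#'
#' Shannon entropy of the AU frequency distribution within the context,
#' `H = -sum(p * ln p)`, exponentiated to `D = exp(H)`: the effective
#' number of action units, between 1 (a single AU) and the number of AUs
#' observed (even usage). Contexts with no events have undefined entropy
#' and are excluded.
#'
#' @param ledger A [build_ledger()] result.
#' @return Data.frame `subject_id, context, n_aus, diversity`.
#' @export
diversity_per_context <- function(ledger) {
  ac <- ledger$au_counts
  if (is.null(ac) || !nrow(ac))
    return(data.frame(subject_id = character(0), context = character(0),
                      n_aus = numeric(0), diversity = numeric(0)))
  key <- paste(ac$subject_id, ac$context, sep = "\r")
  tot <- stats::ave(ac$n, key, FUN = sum)
  p <- ac$n / tot
  contrib <- -p * log(p)
  h <- tapply(contrib, key, sum)
  n_aus <- tapply(contrib, key, length)
  parts <- strsplit(names(h), "\r", fixed = TRUE)
  out <- data.frame(
    subject_id = vapply(parts, `[`, character(1), 1),
    context = vapply(parts, `[`, character(1), 2),
    n_aus = as.numeric(n_aus), diversity = exp(as.numeric(h)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Context-averaged expressivity profile
#'
#' The final expressivity score per subject is the unweighted mean across
#' contexts of the per-context rate, duration and diversity, so each
#' context contributes equal weight. AU proportions are computed on the
#' pooled event counts (`AU_x / f`).
#'
#' @param ledger A [build_ledger()] result.
#' @param min_context_seconds Contexts with less true observation time are
#'   excluded (0 = keep all observed contexts).
#' @param duration_method Passed to [rate_duration_per_context()].
#' @return List of class `maqsoc_profile`: `profile` (data.frame
#'   `subject_id, au_rate, au_duration, au_diversity, n_contexts, n_events,
#'   t_total`), `proportions` (subjects x 17 matrix), `per_context`.
#' @export
aggregate_profile <- function(ledger, min_context_seconds = 0,
                              duration_method = "sum") {
  vocab <- maqfacs_vocabulary()$code
  rd <- rate_duration_per_context(ledger, duration_method)
  rd <- rd[rd$t >= min_context_seconds, ]
  if (!nrow(rd)) stop("no context passes the observation-time filter")
  dv <- diversity_per_context(ledger)
  dv <- dv[paste(dv$subject_id, dv$context) %in%
           paste(rd$subject_id, rd$context), ]
  subjects <- sort(unique(rd$subject_id))  # only subjects with kept contexts
  keep_key <- paste(rd$subject_id, rd$context)
  ac <- ledger$au_counts
  ac <- ac[paste(ac$subject_id, ac$context) %in% keep_key, ]
  prop <- matrix(0, length(subjects), length(vocab),
                 dimnames = list(subjects, vocab))
  pooled <- tapply(ac$n, list(factor(ac$subject_id, levels = subjects),
                              factor(ac$au_code, levels = vocab)), sum)
  pooled[is.na(pooled)] <- 0
  prop[] <- pooled
  tot <- rowSums(prop)
  prop[tot > 0, ] <- prop[tot > 0, , drop = FALSE] / tot[tot > 0]
  prof <- data.frame(
    subject_id = subjects,
    au_rate = as.numeric(tapply(rd$rate,
      factor(rd$subject_id, levels = subjects), mean)),
    au_duration = as.numeric(tapply(rd$duration_pct,
      factor(rd$subject_id, levels = subjects), mean)),
    au_diversity = as.numeric(tapply(dv$diversity,
      factor(dv$subject_id, levels = subjects), mean)),
    n_contexts = as.numeric(tapply(rd$context,
      factor(rd$subject_id, levels = subjects), length)),
    n_events = as.numeric(tot),
    t_total = as.numeric(tapply(rd$t,
      factor(rd$subject_id, levels = subjects), sum)),
    stringsAsFactors = FALSE)
  structure(list(profile = prof, proportions = prop,
                 per_context = list(rate_duration = rd, diversity = dv)),
            class = "maqsoc_profile")
}

#' Expressivity profiles straight from event tables
#'
#' @inheritParams build_ledger
#' @inheritParams aggregate_profile
#' @return A `maqsoc_profile` (see [aggregate_profile()]).
#' @export
expressivity_profiles <- function(au_events, context_timeline,
                                  config = run_config(),
                                  min_context_seconds = 0,
                                  duration_method = "sum") {
  aggregate_profile(build_ledger(au_events, context_timeline, config),
                    min_context_seconds, duration_method)
}

#' Robustness of expressivity scores to thin contexts
#'
#' Recomputes the profiles excluding contexts with less than
#' `min_seconds` of true observation time and reports the Pearson
#' correlation between original and filtered scores across subjects, per
#' measure. Subjects losing all contexts are flagged and excluded from the
#' correlations.
#'
#' @param ledger A [build_ledger()] result.
#' @param min_seconds Exclusion threshold in seconds (default 60).
#' @return List: `original`, `filtered` (profiles), `dropped_subjects`,
#'   and `correlations` (named vector over rate/duration/diversity).
#' @export
robustness_filter <- function(ledger, min_seconds = 60) {
  orig <- aggregate_profile(ledger, 0)
  ok_subjects <- unique(
    ledger$context$subject_id[ledger$context$t >= min_seconds])
  dropped <- setdiff(orig$profile$subject_id, ok_subjects)
  if (length(dropped))
    warning("subjects with no context above the threshold: ",
            paste(dropped, collapse = ", "))
  filt <- aggregate_profile(ledger, min_seconds)
  common <- intersect(orig$profile$subject_id, filt$profile$subject_id)
  o <- orig$profile[match(common, orig$profile$subject_id), ]
  f <- filt$profile[match(common, filt$profile$subject_id), ]
  cors <- vapply(c("au_rate", "au_duration", "au_diversity"), function(mm) {
    if (stats::sd(o[[mm]]) == 0 || stats::sd(f[[mm]]) == 0) return(NA_real_)
    stats::cor(o[[mm]], f[[mm]])
  }, numeric(1))
  list(original = orig, filtered = filt, dropped_subjects = dropped,
       correlations = cors)
}
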