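# Prioritization: IUCN status grouping, percentile exposure thresholds,
# candidate flagging, and congruence with status groups.

.STATUS_GROUPS <- c(
  EX = "Threatened", EW = "Threatened", RE = "Threatened",
  CR = "Threatened", EN = "Threatened",
  VU = "Vulnerable",
  NT = "Not Threatened", LC = "Not Threatened",
  "LR/lc" = "Not Threatened", "LR/cd" = "Not Threatened",
  "LR/nt" = "Not Threatened",
  DD = "Data Deficient", NE = "Not Evaluated")

#' Map an IUCN Red List code to its conservation status group
#'
#' Grouping: Threatened = EX, EW, RE, CR, EN; Vulnerable = VU;
#' Not Threatened = LC, NT and the LR variants; DD maps to Data Deficient;
#' missing codes (`NA` or empty) to Not Evaluated.
#'
#' @param code character vector of IUCN category codes.
#' @return Character vector of groups.
#' @export
status_group <- function(code) {
  out <- ifelse(is.na(code) | !nzchar(code), "Not Evaluated",
                unname(.STATUS_GROUPS[code]))
  bad <- !is.na(code) & nzchar(code) & !(code %in% names(.STATUS_GROUPS))
  if (any(bad))
    stop("unrecognized IUCN codes: ", paste(unique(code[bad]), collapse = ", "))
  out
}

#' Per-threat exposure thresholds at the 95th percentile
#'
#' Computes, per rate column, the empirical `q` quantile over all
#' non-removed species (zeros from non-significant trends included), using
#' linear interpolation (quantile type 7). Bidirectional columns also get
#' the lower `1 - q` tail, since both increases and decreases are threats.
#'
#' @param rrc wide rate table (`species` + numeric rate columns).
#' @param q upper quantile level (default 0.95).
#' @param bidirectional character vector naming which rate columns are
#'   bidirectional (get a lower threshold too).
#' @param min_n minimum species with non-missing rates per column.
#' @return Data frame `(column, lower, upper, q)`, `lower = NA` for
#'   unidirectional columns.
#' @export
compute_thresholds <- function(rrc, q = 0.95, bidirectional = character(0),
                               min_n = 20) {
  num_cols <- setdiff(names(rrc), "species")
  rows <- lapply(num_cols, function(cl) {
    v <- rrc[[cl]][!is.na(rrc[[cl]])]
    if (length(v) < min_n)
      stop("only ", length(v), " species with rates for '", cl,
           "'; need at least ", min_n)
    upper <- stats::quantile(v, q, type = 7, names = FALSE)
    lower <- if (cl %in% bidirectional)
      stats::quantile(v, 1 - q, type = 7, names = FALSE) else NA_real_
    data.frame(column = cl, lower = lower, upper = upper, q = q,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Flag priority candidates for Red List re-evaluation
#'
#' A species is a candidate for a rate column when its rate strictly
#' exceeds the upper threshold (or, for bidirectional columns, also when it
#' falls strictly below the lower threshold). Per-column flags are
#' collapsed to per-threat flags via `threat_of` (so the climate variables
#' count as one threat), `n_threats_flagged` counts flagged threats, and
#' minimal-area species are priority by default with a distinct reason.
#'
#' @param rrc wide rate table (`species` + rate columns).
#' @param thresholds output of [compute_thresholds()].
#' @param minimal_species character vector of minimal-area species ids.
#' @param threat_of named character vector mapping rate columns to threat
#'   names; defaults to each column being its own threat.
#' @return Data frame with `species`, one logical `flag_<column>` per
#'   column, one logical `threat_<name>` per threat, `n_threats_flagged`,
#'   `priority`, `priority_reason` (`"threat"`, `"minimal_area"`, `""`).
#' @export
flag_candidates <- function(rrc, thresholds, minimal_species = character(0),
                            threat_of = NULL) {
  num_cols <- thresholds$column
  if (is.null(threat_of)) threat_of <- stats::setNames(num_cols, num_cols)
  out <- data.frame(species = rrc$species, stringsAsFactors = FALSE)
  for (i in seq_along(num_cols)) {
    cl <- num_cols[i]
    v <- rrc[[cl]]
    up <- thresholds$upper[i]; lo <- thresholds$lower[i]
    fl <- !is.na(v) & (v > up | (!is.na(lo) & v < lo))
    out[[paste0("flag_", cl)]] <- fl
  }
  threats <- unique(unname(threat_of[num_cols]))
  for (th in threats) {
    cols <- num_cols[threat_of[num_cols] == th]
    out[[paste0("threat_", th)]] <-
      Reduce(`|`, lapply(cols, function(cl) out[[paste0("flag_", cl)]]))
  }
  out$n_threats_flagged <-
    rowSums(as.matrix(out[paste0("threat_", threats)]))
  out$priority <- out$n_threats_flagged > 0
  out$priority_reason <- ifelse(out$priority, "threat", "")
  if (length(minimal_species)) {
    extra <- data.frame(species = setdiff(minimal_species, out$species),
                        stringsAsFactors = FALSE)
    if (nrow(extra)) {
      for (cl in setdiff(names(out), "species"))
        extra[[cl]] <- if (is.logical(out[[cl]])) FALSE
        else if (is.numeric(out[[cl]])) 0 else ""
      out <- rbind(out, extra)
    }
    mm <- out$species %in% minimal_species
    out$priority[mm] <- TRUE
    out$priority_reason[mm] <- "minimal_area"
  }
  rownames(out) <- NULL
  out
}

#' Cross-tabulate priority candidates against status groups
#'
#' Counts candidates per conservation status group, the share of all
#' candidates in each group, and the share of each group that is a
#' candidate. Species without a status record are counted as Not
#' Evaluated.
#'
#' @param candidates output of [flag_candidates()] (uses `species`,
#'   `priority`).
#' @param status data frame `(species, category)`.
#' @return Data frame `(group, n_species, n_candidates, pct_of_candidates,
#'   pct_of_group)`.
#' @export
congruence_summary <- function(candidates, status) {
  m <- merge(candidates[, c("species", "priority")], status,
             by = "species", all.x = TRUE)
  m$group <- status_group(m$category)
  groups <- c("Threatened", "Vulnerable", "Not Threatened",
              "Data Deficient", "Not Evaluated")
  n_cand_total <- sum(m$priority)
  rows <- lapply(groups, function(gr) {
    sub <- m[m$group == gr, , drop = FALSE]
    nc <- sum(sub$priority)
    data.frame(group = gr, n_species = nrow(sub), n_candidates = nc,
               pct_of_candidates = if (n_cand_total > 0)
                 100 * nc / n_cand_total else 0,
               pct_of_group = if (nrow(sub) > 0) 100 * nc / nrow(sub) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
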