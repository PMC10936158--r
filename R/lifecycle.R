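#' Ordered life-cycle stages for longitudinal observation tables
#' @return Character vector, in progression order.
#' @export
lifecycle_stages <- function() {
  c("juvenile", "adult", "pre_reproductive", "reproductive",
    "offspring_emerged")
}

validate_lifecycle <- function(table) {
  req <- c("cell_id", "day", "stage")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop("lifecycle table lacks columns: ", paste(miss, collapse = ", "))
  if (any(table$day < 0)) stop("days must be non-negative")
  bad <- unlist(lapply(split(table$day, table$cell_id),
                       function(d) any(diff(d) <= 0)))
  if (any(bad))
    stop("non-monotone observation days for cell(s): ",
         paste(names(bad)[bad], collapse = ", "))
  invisible(table)
}

#' Per-cell stage durations and total life duration
#'
#' Observations may be sparse (biweekly outside reproductive phases); the
#' last observed stage is carried forward day by day, so the duration of a
#' stage is the number of days from its first observation to the first
#' observation of the next stage. Total life duration runs from emergence
#' (day 0) to the first `offspring_emerged` observation; cells never
#' observed reproducing get `NA` and a flag. Cells flagged as deviating
#' (budding, reproductive arrest) via an optional logical `deviant` column
#' are excluded from the output.
#'
#' @param table Data frame with columns `cell_id`, `day` (integer days
#'   since emergence, strictly increasing per cell), `stage` (see
#'   [lifecycle_stages()]); optional `reproductive_type`, `deviant`.
#' @param max_gap_days Observation gaps longer than this trigger a warning.
#' @return Data frame, one row per cell: duration of each stage in days,
#'   `total_days`, `reproductive_type` (if present), and `complete`
#'   (FALSE when the terminal stage was never observed).
#' @export
stage_durations <- function(table, max_gap_days = 14) {
  validate_lifecycle(table)
  if (!is.null(table$deviant)) table <- table[!table$deviant, , drop = FALSE]
  stages <- lifecycle_stages()
  cells <- split(table, table$cell_id)
  rows <- lapply(cells, function(tc) {
    tc <- tc[order(tc$day), , drop = FALSE]
    if (nrow(tc) > 1 && any(diff(tc$day) > max_gap_days))
      warning("cell ", tc$cell_id[1], ": observation gap exceeds ",
              max_gap_days, " days")
    first_seen <- vapply(stages, function(s) {
      i <- which(tc$stage == s)
      if (length(i)) tc$day[min(i)] else NA_real_
    }, numeric(1))
    complete <- !is.na(first_seen["offspring_emerged"])
    if (nrow(tc) == 1) complete <- FALSE
    durs <- rep(NA_real_, length(stages) - 1)
    names(durs) <- paste0(stages[-length(stages)], "_days")
    for (k in seq_len(length(stages) - 1)) {
      if (is.na(first_seen[k])) next
      nxt <- first_seen[(k + 1):length(stages)]
      nxt <- nxt[!is.na(nxt)]
      if (length(nxt)) durs[k] <- nxt[1] - first_seen[k]
    }
    total <- if (complete) first_seen[["offspring_emerged"]] - tc$day[1]
             else NA_real_
    out <- data.frame(cell_id = tc$cell_id[1], t(durs),
                      total_days = total, complete = complete)
    if (!is.null(tc$reproductive_type))
      out$reproductive_type <- tc$reproductive_type[nrow(tc)]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a cell's emergence timing from its total life duration
#'
#' Early emergers complete their life cycle in under 25 days, middle
#' emergers in 25-35 days (both boundaries inclusive), and late emergers in
#' more than 35 days.
#'
#' @param total_days Positive total life duration(s) in days.
#' @return Character vector in `{"early", "middle", "late"}`.
#' @export
classify_emergence <- function(total_days) {
  if (any(total_days <= 0, na.rm = TRUE))
    stop("total life duration must be positive")
  ifelse(total_days < 25, "early", ifelse(total_days <= 35, "middle",
                                          "late"))
}

#' Reproductive-type transition percentages
#'
#' For emergers of each parental reproductive type, the percentage that
#' developed into each reproductive type themselves. Percentages are
#' rounded to the nearest integer for display; raw counts are retained.
#'
#' @param table Data frame with one row per emerger: `parent_type` and
#'   `own_type` (each `"type1"`/`"type2"`; `NA` own types are dropped), or
#'   a lifecycle observation table carrying `parent_type` and
#'   `reproductive_type` columns (the cell's final non-NA value is used).
#' @return Data frame: `parent_type`, `own_type`, `count`, `total`,
#'   `percent`.
#' @export
transition_percentages <- function(table) {
  if (!is.null(table$own_type)) {
    df <- data.frame(parent_type = table$parent_type,
                     own_type = table$own_type)
  } else {
    if (is.null(table$parent_type) || is.null(table$reproductive_type))
      stop("need parent_type and own_type (or reproductive_type) columns")
    per_cell <- lapply(split(table, table$cell_id), function(tc) {
      own <- tc$reproductive_type[!is.na(tc$reproductive_type)]
      data.frame(parent_type = tc$parent_type[1],
                 own_type = if (length(own)) own[length(own)] else NA)
    })
    df <- do.call(rbind, per_cell)
  }
  df <- df[!is.na(df$own_type) & !is.na(df$parent_type), , drop = FALSE]
  if (!nrow(df)) {
    warning("no emergers with known parent and own reproductive type")
    return(data.frame(parent_type = character(), own_type = character(),
                      count = integer(), total = integer(),
                      percent = numeric()))
  }
  out <- list()
  for (pt in unique(df$parent_type)) {
    sub <- df[df$parent_type == pt, , drop = FALSE]
    for (ot in unique(df$own_type)) {
      cnt <- sum(sub$own_type == ot)
      out[[length(out) + 1]] <- data.frame(
        parent_type = pt, own_type = ot, count = cnt, total = nrow(sub),
        percent = round(100 * cnt / nrow(sub)))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flask synchrony index
#'
#' For each observation day, the fraction of cells in the modal life stage;
#' the index is the mean of those daily fractions. 1 means every cell is
#' always in the same stage; with k stages the index cannot fall below 1/k.
#'
#' @param flask_table Data frame with `day` and `stage` columns, one row
#'   per cell per day.
#' @return List with `per_day` (data frame: `day`, `n_cells`,
#'   `modal_fraction`) and `index` (their mean).
#' @export
synchrony_index <- function(flask_table) {
  if (!nrow(flask_table)) stop("empty flask table")
  days <- split(flask_table, flask_table$day)
  per_day <- do.call(rbind, lapply(days, function(d) {
    tab <- table(d$stage)
    data.frame(day = d$day[1], n_cells = nrow(d),
               modal_fraction = max(tab) / nrow(d))
  }))
  rownames(per_day) <- NULL
  list(per_day = per_day, index = mean(per_day$modal_fraction))
}

#' Simulate a longitudinal observation cohort
#'
#' Draws per-cell stage durations from normal distributions (truncated at
#' one day), assigns each emerger's own reproductive type from its
#' parent's type via the cross-type transition probabilities, and emits a
#' daily observation table in the [stage_durations()] schema. Default
#' duration parameters put Type 2 emergers at a 25 +/- 3 day total life
#' cycle and Type 1 emergers at 31 +/- 10 days, partitioned across the
#' four pre-emergence stages.
#'
#' @param n_cells Number of cells.
#' @param parent_type Parent reproductive type for the whole cohort
#'   (`"type1"`, `"type2"`, or `"mixed"`).
#' @param p_switch Named list: probability that a type-1 emerger matures
#'   into a type-2 reproductive cell and vice versa (defaults 0.72 and
#'   0.93).
#' @param duration_means,duration_sds Named lists (`type1`, `type2`) of
#'   length-4 stage duration means/sds in days (juvenile, adult,
#'   pre_reproductive, reproductive).
#' @param rng_seed Integer seed.
#' @return Data frame: `cell_id`, `parent_type`, `reproductive_type`,
#'   `day`, `stage`.
#' @export
simulate_lifecycle_cohort <- function(
    n_cells = 96, parent_type = "mixed",
    p_switch = list(type1 = 0.72, type2 = 0.93),
    duration_means = list(type1 = c(10, 12, 5, 4), type2 = c(8, 10, 4, 3)),
    duration_sds = list(type1 = c(4, 4, 1.5, 1.2),
                        type2 = c(1.4, 1.6, 1.0, 0.8)),
    rng_seed = 1L) {
  set.seed(rng_seed)
  stages <- lifecycle_stages()
  rows <- list()
  for (i in seq_len(n_cells)) {
    pt <- if (parent_type == "mixed")
      sample(c("type1", "type2"), 1) else parent_type
    own <- if (pt == "type1") {
      if (stats::runif(1) < p_switch$type1) "type2" else "type1"
    } else {
      if (stats::runif(1) < p_switch$type2) "type1" else "type2"
    }
    # the emerger's own developmental tempo follows its own type
    mu <- duration_means[[own]]; sd <- duration_sds[[own]]
    durs <- pmax(1, round(stats::rnorm(4, mu, sd)))
    bounds <- cumsum(c(0, durs))
    days <- 0:bounds[5]
    stage <- cut(days, breaks = c(bounds, Inf), labels = stages,
                 right = FALSE)
    rows[[i]] <- data.frame(
      cell_id = sprintf("cell%03d", i), parent_type = pt,
      reproductive_type = own, day = days, stage = as.character(stage))
  }
  do.call(rbind, rows)
}
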