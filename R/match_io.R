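# Canonical point-by-point schema. One row per point; _1/_2 suffixes are the
# two players. Indicator columns are tri-state: 0, 1, or NA (absent).
canonical_columns <- function() {
  c("match_id", "point_no", "set_no", "game_no", "elapsed_seconds",
    "server", "point_victor", "game_victor", "set_victor",
    "ace_1", "ace_2", "serve_winner_1", "serve_winner_2",
    "winner_1", "winner_2", "double_fault_1", "double_fault_2",
    "unf_err_1", "unf_err_2", "net_pt_1", "net_pt_2",
    "net_pt_won_1", "net_pt_won_2", "break_pt_1", "break_pt_2",
    "break_pt_won_1", "break_pt_won_2", "distance_run_1", "distance_run_2",
    "rally_count", "serve_speed")
}

# External-name -> canonical-name map for the public Grand Slam
# point-by-point dialect. Shipped as inst/extdata/dialect_slam_pbp.csv; the
# copy here is the authoritative fallback so reading works without the file.
slam_pbp_map <- function() {
  c(match_id = "match_id", ElapsedTime = "elapsed_seconds",
    SetNo = "set_no", GameNo = "game_no", PointNumber = "point_no",
    PointServer = "server", PointWinner = "point_victor",
    GameWinner = "game_victor", SetWinner = "set_victor",
    P1Ace = "ace_1", P2Ace = "ace_2",
    P1Winner = "winner_1", P2Winner = "winner_2",
    P1DoubleFault = "double_fault_1", P2DoubleFault = "double_fault_2",
    P1UnfErr = "unf_err_1", P2UnfErr = "unf_err_2",
    P1NetPoint = "net_pt_1", P2NetPoint = "net_pt_2",
    P1NetPointWon = "net_pt_won_1", P2NetPointWon = "net_pt_won_2",
    P1BreakPoint = "break_pt_1", P2BreakPoint = "break_pt_2",
    P1BreakPointWon = "break_pt_won_1", P2BreakPointWon = "break_pt_won_2",
    P1DistanceRun = "distance_run_1", P2DistanceRun = "distance_run_2",
    RallyCount = "rally_count", Speed_KMH = "serve_speed")
}

#' Construct a single-match record
#'
#' A `match_record` holds the ordered point table of one match in the
#' canonical schema plus light metadata. Most users obtain these from
#' [read_points()] or [simulate_match()] rather than building them directly.
#'
#' @param points data frame with at least `match_id`, `server`,
#'   `point_victor`; missing canonical columns are added as `NA`.
#' @param court_type one of `"grass"`, `"clay"`, `"hard"`.
#' @param best_of 3 or 5.
#' @param players length-2 character vector of player labels.
#' @param tournament optional tournament label.
#' @return An object of class `match_record` with elements `match_id`,
#'   `points`, `meta`.
#' @export
match_record <- function(points, court_type = "hard", best_of = 5,
                         players = c("player 1", "player 2"),
                         tournament = NA_character_) {
  stopifnot(is.data.frame(points),
            all(c("match_id", "server", "point_victor") %in% names(points)))
  points <- as.data.frame(points, stringsAsFactors = FALSE)
  for (col in setdiff(canonical_columns(), names(points)))
    points[[col]] <- NA
  if (all(is.na(points$point_no)))
    points$point_no <- seq_len(nrow(points))
  extras <- setdiff(names(points), canonical_columns())
  points <- points[, c(canonical_columns(), extras), drop = FALSE]
  points <- points[order(points$point_no), , drop = FALSE]
  rownames(points) <- NULL
  m <- list(match_id = as.character(points$match_id[1L]),
            points = points,
            meta = list(court_type = match.arg(court_type,
                                               c("hard", "grass", "clay")),
                        best_of = as.integer(best_of),
                        players = players,
                        tournament = tournament))
  class(m) <- "match_record"
  m
}

#' @export
print.match_record <- function(x, ...) {
  cat(sprintf("<match_record> %s: %d points, best of %d, %s court\n",
              x$match_id, nrow(x$points), x$meta$best_of, x$meta$court_type))
  invisible(x)
}

new_corpus <- function(matches) {
  stopifnot(all(vapply(matches, inherits, logical(1), "match_record")))
  names(matches) <- vapply(matches, `[[`, character(1), "match_id")
  class(matches) <- "match_corpus"
  matches
}

#' @export
print.match_corpus <- function(x, ...) {
  cat(sprintf("<match_corpus> %d matches, %d points\n", length(x),
              sum(vapply(x, function(m) nrow(m$points), integer(1)))))
  invisible(x)
}

# "H:MM:SS" (hours may exceed 24 in the source data) -> seconds. Numeric
# strings pass through. Unparseable values -> NA with one warning per file.
parse_clock <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  hms <- grepl("^\\d+:\\d{1,2}:\\d{1,2}(\\.\\d+)?$", x)
  if (any(hms)) {
    parts <- strsplit(x[hms], ":", fixed = TRUE)
    out[hms] <- vapply(parts, function(p) {
      p <- as.numeric(p)
      p[1] * 3600 + p[2] * 60 + p[3]
    }, numeric(1))
  }
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad))
    warning(sum(bad), " unparseable clock value(s); elapsed_seconds set NA",
            call. = FALSE)
  out
}

#' Read point-by-point match tables from CSV
#'
#' Reads a CSV in either the canonical snake_case dialect or the public
#' Grand Slam point-by-point dialect (`"slam_pbp"`, CamelCase columns with
#' an `ElapsedTime` clock in `H:MM:SS`), and splits it into one
#' [match_record()] per distinct `match_id`.
#'
#' Indicator columns absent from the file are recorded as absent (`NA`), not
#' as zero; downstream consumers treat absence explicitly. Unknown columns
#' are preserved untouched after the canonical ones.
#'
#' @param path CSV file with a header.
#' @param dialect `"canonical"` or `"slam_pbp"`.
#' @param court_type,best_of metadata applied to every match read.
#' @return A `match_corpus` (list of `match_record`).
#' @seealso [write_points()], [validate_match()]
#' @export
read_points <- function(path, dialect = c("canonical", "slam_pbp"),
                        court_type = "hard", best_of = 5) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (dialect == "slam_pbp") {
    map <- slam_pbp_map()
    hit <- names(df) %in% names(map)
    names(df)[hit] <- unname(map[names(df)[hit]])
  }
  mandatory <- c("match_id", "server", "point_victor")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if ("elapsed_seconds" %in% names(df))
    df$elapsed_seconds <- parse_clock(df$elapsed_seconds)
  for (col in intersect(canonical_columns(), names(df))) {
    if (col %in% c("match_id")) next
    if (is.character(df[[col]]))
      df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  new_corpus(lapply(split(df, df$match_id), match_record,
                    court_type = court_type, best_of = best_of))
}

#' Write a match corpus to a canonical-dialect CSV
#'
#' Emits UTF-8, LF line endings, RFC-4180 quoting, a stable column order,
#' and empty fields for `NA`, so that `read_points()` round-trips the
#' collection losslessly and `write(read(write(x)))` is byte-identical.
#'
#' @param corpus a `match_corpus` or single `match_record`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_points <- function(corpus, path) {
  if (inherits(corpus, "match_record")) corpus <- new_corpus(list(corpus))
  stopifnot(inherits(corpus, "match_corpus"))
  tabs <- lapply(unname(corpus), function(m) m$points[, canonical_columns()])
  df <- if (length(tabs)) do.call(rbind, tabs) else
    as.data.frame(stats::setNames(rep(list(logical(0)),
                                      length(canonical_columns())),
                                  canonical_columns()))
  con <- tryCatch(file(path, open = "wb"), error = function(e)
    stop("cannot write to path: ", path, call. = FALSE))
  on.exit(close(con))
  fmt <- function(v) {
    out <- vapply(v, function(x) {
      if (is.na(x)) "" else if (is.character(x)) x
      else format(x, scientific = FALSE, trim = TRUE, digits = 15)
    }, character(1))
    needs <- grepl('[",\n]', out)
    out[needs] <- paste0('"', gsub('"', '""', out[needs]), '"')
    out
  }
  lines <- paste(canonical_columns(), collapse = ",")
  if (nrow(df)) {
    cells <- vapply(canonical_columns(), function(cl) fmt(df[[cl]]),
                    character(nrow(df)))
    if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
    lines <- c(lines, apply(cells, 1L, paste, collapse = ","))
  }
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Validate a match record against the schema invariants
#'
#' Checks the per-point invariants of the canonical schema: monotone point
#' and set numbering, aces only winning (and double faults only losing) the
#' server's point, `*_won` flags implying the base flag, and game/set
#' victors appearing only on the final point of their game. Violations are
#' returned as data, never raised: flagged matches still flow through the
#' momentum engine.
#'
#' @param m a `match_record`.
#' @return A data frame with columns `rule`, `point_no`, `message`;
#'   zero rows when the record is clean.
#' @export
validate_match <- function(m) {
  stopifnot(inherits(m, "match_record"))
  pts <- m$points
  out <- list()
  bad <- function(rule, point_no, message)
    data.frame(rule = rule, point_no = point_no, message = message,
               stringsAsFactors = FALSE)
  n <- nrow(pts)
  if (n > 1L) {
    i <- which(diff(pts$point_no) <= 0)
    if (length(i))
      out[[length(out) + 1L]] <- bad("point_no_monotone", pts$point_no[i + 1L],
                                     "point_no not strictly increasing")
    i <- which(diff(pts$set_no) < 0)
    if (length(i))
      out[[length(out) + 1L]] <- bad("set_no_monotone", pts$point_no[i + 1L],
                                     "set_no decreases")
  }
  for (x in 1:2) {
    df_col <- pts[[paste0("double_fault_", x)]]
    i <- which(!is.na(df_col) & df_col == 1 &
                 (pts$server != x | pts$point_victor == x))
    if (length(i))
      out[[length(out) + 1L]] <- bad("double_fault_server_loses",
                                     pts$point_no[i],
                                     "double fault only by the server, and the server loses the point")
    ace <- pts[[paste0("ace_", x)]]
    i <- which(!is.na(ace) & ace == 1 &
                 (pts$server != x | pts$point_victor != x))
    if (length(i))
      out[[length(out) + 1L]] <- bad("ace_server_wins", pts$point_no[i],
                                     "ace implies the server wins the point")
    for (base in c("net_pt", "break_pt")) {
      won <- pts[[paste0(base, "_won_", x)]]
      has <- pts[[paste0(base, "_", x)]]
      i <- which(!is.na(won) & won == 1 & (is.na(has) | has != 1))
      if (length(i))
        out[[length(out) + 1L]] <- bad(paste0(base, "_won_implies_", base),
                                       pts$point_no[i],
                                       paste0(base, "_won without ", base))
    }
  }
  gv <- pts$game_victor
  if (!all(is.na(gv))) {
    key <- paste(pts$set_no, pts$game_no)
    last_of_game <- !duplicated(key, fromLast = TRUE)
    i <- which(!is.na(gv) & gv != 0 & !last_of_game)
    if (length(i))
      out[[length(out) + 1L]] <- bad("game_victor_last_point",
                                     pts$point_no[i],
                                     "game_victor nonzero before the game's last point")
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(rule = character(0), point_no = numeric(0),
               message = character(0), stringsAsFactors = FALSE)
}
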