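#' Construct and validate an IntelliCage event dataset
#'
#' The canonical container for one cage run: an animal roster plus the three
#' linked event tables produced by the cage hardware (corner visits, nose
#' pokes, lick bursts). All timestamps are seconds since protocol start
#' (`t0`), with t = 0 anchored at lights-on.
#'
#' @param animals data.frame with columns `animal_id`, `genotype`
#'   ("NonTg"/"TG"), `cage_id`, and optionally `status` ("active"/"removed")
#'   and `removal_day`.
#' @param visits data.frame with columns `visit_id`, `animal_id`, `corner`,
#'   `t_start`, `t_end`.
#' @param pokes data.frame with columns `visit_id`, `side` ("left"/"right"),
#'   `t`.
#' @param licks data.frame with columns `visit_id`, `t`, `n_licks` (licks in
#'   a burst; summed for Total Licks).
#' @param t0 numeric origin timestamp (default 0).
#' @param lights_on,lights_off clock hours of the light phase (06:00/18:00).
#' @param validate run full invariant checks (default TRUE).
#' @return an object of class `ic_dataset`.
#' @export
ic_dataset <- function(animals, visits, pokes, licks, t0 = 0,
                       lights_on = 6, lights_off = 18, validate = TRUE) {
  ds <- structure(
    list(
      animals = normalize_roster(animals),
      visits  = as.data.frame(visits)[, c("visit_id", "animal_id", "corner",
                                          "t_start", "t_end"), drop = FALSE],
      pokes   = as.data.frame(pokes)[, c("visit_id", "side", "t"), drop = FALSE],
      licks   = as.data.frame(licks)[, c("visit_id", "t", "n_licks"), drop = FALSE],
      t0 = t0, lights_on = lights_on, lights_off = lights_off
    ),
    class = "ic_dataset"
  )
  ds <- sort_dataset(ds)
  if (validate) validate_dataset(ds)
  ds
}

normalize_roster <- function(animals) {
  animals <- as.data.frame(animals)
  if (is.null(animals$status)) animals$status <- "active"
  if (is.null(animals$removal_day)) animals$removal_day <- NA_integer_
  animals[, c("animal_id", "genotype", "cage_id", "status", "removal_day")]
}

sort_dataset <- function(ds) {
  ds$animals <- ds$animals[order(ds$animals$animal_id), , drop = FALSE]
  ds$visits  <- ds$visits[order(ds$visits$t_start, ds$visits$visit_id), , drop = FALSE]
  ds$pokes   <- ds$pokes[order(ds$pokes$t, ds$pokes$visit_id), , drop = FALSE]
  ds$licks   <- ds$licks[order(ds$licks$t, ds$licks$visit_id), , drop = FALSE]
  rownames(ds$animals) <- rownames(ds$visits) <- NULL
  rownames(ds$pokes) <- rownames(ds$licks) <- NULL
  ds
}

#' Validate all dataset invariants
#'
#' Checks referential integrity (every poke/lick references an existing
#' visit and lies inside its time span), visit sanity (t_start < t_end,
#' corners in 1..4, per-animal non-overlap), roster uniqueness, and the
#' status/removal_day consistency rule.
#'
#' @param ds an `ic_dataset`.
#' @return the dataset, invisibly; errors describe the first violation found.
#' @export
validate_dataset <- function(ds) {
  an <- ds$animals; v <- ds$visits; p <- ds$pokes; l <- ds$licks
  if (anyDuplicated(an$animal_id))
    stop_cage("integrity error: duplicated animal_id in roster")
  bad_status <- xor(an$status == "removed", !is.na(an$removal_day))
  if (any(bad_status))
    stop_cage("integrity error: removal_day must be present iff status = removed (animals: %s)",
              paste(an$animal_id[bad_status], collapse = ", "))
  if (nrow(v)) {
    if (anyDuplicated(v$visit_id))
      stop_cage("integrity error: duplicated visit_id")
    if (any(!v$animal_id %in% an$animal_id))
      stop_cage("integrity error: visit for unknown animal_id")
    if (any(v$t_start >= v$t_end))
      stop_cage("invariant violated: t_start >= t_end for visit_id %s",
                paste(v$visit_id[v$t_start >= v$t_end], collapse = ", "))
    if (any(!v$corner %in% 1:4))
      stop_cage("invariant violated: corner outside 1..4")
    if (any(v$t_start < ds$t0))
      stop_cage("invariant violated: visit before protocol start t0")
    ov <- unlist(lapply(split(v, v$animal_id), function(vv) {
      vv <- vv[order(vv$t_start), ]
      n <- nrow(vv)
      if (n < 2) return(integer(0))
      vv$visit_id[c(vv$t_start[-1] < vv$t_end[-n], FALSE)]
    }))
    if (length(ov))
      stop_cage("invariant violated: overlapping visits for one animal (visit_id %s)",
                paste(ov, collapse = ", "))
  }
  check_child <- function(tab, what) {
    if (!nrow(tab)) return()
    idx <- match(tab$visit_id, v$visit_id)
    if (anyNA(idx))
      stop_cage("integrity error: %s rows reference unknown visit_id: %s",
                what, paste(unique(tab$visit_id[is.na(idx)]), collapse = ", "))
    out <- tab$t < v$t_start[idx] | tab$t > v$t_end[idx]
    if (any(out))
      stop_cage("invariant violated: %s outside its visit (visit_id %s)",
                what, paste(unique(tab$visit_id[out]), collapse = ", "))
  }
  check_child(p, "poke")
  check_child(l, "lick")
  if (nrow(l) && any(l$n_licks < 1))
    stop_cage("invariant violated: n_licks must be >= 1")
  invisible(ds)
}

required_columns <- list(
  visits = c("visit_id", "animal_id", "corner", "t_start", "t_end"),
  pokes  = c("visit_id", "side", "t"),
  licks  = c("visit_id", "t", "n_licks"),
  roster = c("animal_id", "genotype", "cage_id")
)

read_tsv_checked <- function(path, what) {
  if (!file.exists(path)) stop_cage("file not found: %s", path)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(required_columns[[what]], names(tab))
  if (length(missing))
    stop_cage("format error in %s: missing column(s) %s",
              path, paste(missing, collapse = ", "))
  tab
}

#' Parse tab-delimited IntelliCage event exports
#'
#' Reads the four linked tab-delimited tables (visits, nose pokes, licks,
#' animal roster) in the layout produced by the cage analysis software
#' export, validates headers and referential integrity, and returns a sorted
#' `ic_dataset`.
#'
#' @param visit_path,poke_path,lick_path,roster_path paths to the TSV files.
#' @param t0 origin timestamp (default 0).
#' @param lights_on,lights_off light-phase clock hours.
#' @return an `ic_dataset`.
#' @export
parse_event_export <- function(visit_path, poke_path, lick_path, roster_path,
                               t0 = 0, lights_on = 6, lights_off = 18) {
  ic_dataset(
    animals = read_tsv_checked(roster_path, "roster"),
    visits  = read_tsv_checked(visit_path, "visits"),
    pokes   = read_tsv_checked(poke_path, "pokes"),
    licks   = read_tsv_checked(lick_path, "licks"),
    t0 = t0, lights_on = lights_on, lights_off = lights_off
  )
}

#' Write event tables as tab-delimited exports
#'
#' Inverse of [parse_event_export()]: writes `visits.tsv`, `pokes.tsv`,
#' `licks.tsv`, `roster.tsv` into a directory.
#'
#' @param ds an `ic_dataset`.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_event_export <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(tab, name) {
    num <- vapply(tab, is.double, logical(1))
    tab[num] <- lapply(tab[num], function(x) sprintf("%.17g", x))
    write.table(tab, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wr(ds$visits, "visits.tsv")
  wr(ds$pokes, "pokes.tsv")
  wr(ds$licks, "licks.tsv")
  wr(ds$animals[, c("animal_id", "genotype", "cage_id")], "roster.tsv")
  invisible(dir)
}

#' Slice a dataset into 24-h analysis days
#'
#' Events are assigned to days by the *entry time* of their visit: a visit
#' straddling a day boundary stays whole in the day it started, and its
#' pokes and licks inherit that day. Slices partition the recording.
#'
#' @param ds an `ic_dataset`.
#' @param n_days number of slices; default spans through the last visit entry.
#' @return list of slices, each `list(day_index, visits, pokes, licks)`.
#' @export
slice_by_day <- function(ds, n_days = NULL) {
  if (!nrow(ds$visits)) stop_cage("cannot slice an empty dataset")
  if (any(ds$visits$t_start < ds$t0))
    stop_cage("visit before protocol start t0")
  vday <- day_of(ds$visits$t_start - ds$t0)
  n_days <- n_days %||% max(vday)
  pday <- vday[match(ds$pokes$visit_id, ds$visits$visit_id)]
  lday <- vday[match(ds$licks$visit_id, ds$visits$visit_id)]
  lapply(seq_len(n_days), function(d) {
    list(
      day_index = d,
      visits = ds$visits[vday == d, , drop = FALSE],
      pokes  = ds$pokes[pday == d, , drop = FALSE],
      licks  = ds$licks[lday == d, , drop = FALSE]
    )
  })
}

STORE_MAGIC <- "# cageRT event store v1"

#' Write / read the single-file relational store
#'
#' Serialises the whole dataset (roster, three event tables, metadata) into
#' one plain-text file with sectioned TSV tables. Numeric columns are
#' written with 17 significant digits so the round trip is bit-exact:
#' `read_store(write_store(x)) == x` on every table.
#'
#' @param ds an `ic_dataset`.
#' @param path file path.
#' @return `write_store`: the path, invisibly. `read_store`: an `ic_dataset`.
#' @export
write_store <- function(ds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(STORE_MAGIC, con)
  writeLines(sprintf("[meta]\nt0=%.17g\nlights_on=%.17g\nlights_off=%.17g\nschema_version=1",
                     ds$t0, ds$lights_on, ds$lights_off), con)
  dump_tab <- function(tab, name) {
    writeLines(sprintf("[table %s rows=%d]", name, nrow(tab)), con)
    num <- vapply(tab, is.double, logical(1))
    tab[num] <- lapply(tab[num], function(x) sprintf("%.17g", x))
    writeLines(paste(names(tab), collapse = "\t"), con)
    if (nrow(tab))
      writeLines(do.call(paste, c(lapply(tab, as.character), sep = "\t")), con)
  }
  dump_tab(ds$animals, "animals")
  dump_tab(ds$visits, "visits")
  dump_tab(ds$pokes, "pokes")
  dump_tab(ds$licks, "licks")
  invisible(path)
}

#' @rdname write_store
#' @export
read_store <- function(path) {
  if (!file.exists(path)) stop_cage("store not found: %s", path)
  lines <- readLines(path)
  if (!length(lines) || lines[1] != STORE_MAGIC)
    stop_cage("corrupt store: bad magic line in %s", path)
  meta_at <- which(lines == "[meta]")
  if (length(meta_at) != 1) stop_cage("corrupt store: missing [meta] section")
  kv <- strsplit(lines[(meta_at + 1):(meta_at + 4)], "=", fixed = TRUE)
  meta <- setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  grab <- function(name) {
    hdr <- grep(sprintf("^\\[table %s rows=", name), lines)
    if (length(hdr) != 1) stop_cage("corrupt store: missing table %s", name)
    n <- as.integer(sub(".*rows=(\\d+)\\]", "\\1", lines[hdr]))
    cols <- strsplit(lines[hdr + 1], "\t", fixed = TRUE)[[1]]
    if (n == 0) {
      tab <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    } else {
      body <- lines[(hdr + 2):(hdr + 1 + n)]
      parts <- strsplit(body, "\t", fixed = TRUE)
      tab <- as.data.frame(setNames(
        lapply(seq_along(cols), function(j) vapply(parts, `[`, "", j)), cols))
    }
    tab
  }
  retype <- function(tab, int_cols, num_cols) {
    for (cc in intersect(int_cols, names(tab)))
      tab[[cc]] <- suppressWarnings(as.integer(tab[[cc]]))
    for (cc in intersect(num_cols, names(tab)))
      tab[[cc]] <- suppressWarnings(as.numeric(tab[[cc]]))
    tab
  }
  animals <- retype(grab("animals"), "removal_day", character(0))
  visits <- retype(grab("visits"), c("visit_id", "corner"), c("t_start", "t_end"))
  pokes <- retype(grab("pokes"), "visit_id", "t")
  licks <- retype(grab("licks"), c("visit_id", "n_licks"), "t")
  ic_dataset(animals, visits, pokes, licks,
             t0 = as.numeric(meta[["t0"]]),
             lights_on = as.numeric(meta[["lights_on"]]),
             lights_off = as.numeric(meta[["lights_off"]]))
}

#' @export
print.ic_dataset <- function(x, ...) {
  cat(sprintf("<ic_dataset> %d animals, %d visits, %d pokes, %d lick bursts (%d licks)\n",
              nrow(x$animals), nrow(x$visits), nrow(x$pokes), nrow(x$licks),
              sum(x$licks$n_licks)))
  invisible(x)
}
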