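#' Write a kinetic scheme (and optional parameters) to a JSON file
#'
#' Versioned, human-editable description: states, transitions (from, to,
#' rate names, charge id, partition, scale factors), constraints and, when
#' supplied, parameter values plus physical constants.
#'
#' @param scheme a `kinetic_scheme`.
#' @param path output file.
#' @param params optional `parameter_set` to embed.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path, params = NULL) {
  doc <- list(
    format = "hcn2kinetics/scheme", version = 1L,
    name = scheme$name,
    states = scheme$states,
    transitions = scheme$transitions,
    constraints = scheme$constraints,
    flags = attr(scheme, "flags"))
  if (!is.null(params))
    doc$params <- list(values = as.list(params$values), VT = params$VT,
                       e = params$e)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a kinetic scheme from a JSON file
#'
#' @param path file written by [write_scheme()] (or hand-authored in the
#'   same schema).
#' @return list with `scheme` and `params` (`NULL` when the file embeds no
#'   parameter values).
#' @export
read_scheme <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "hcn2kinetics/scheme"))
    stop("not a scheme file: ", path)
  tr <- as.data.frame(doc$transitions, stringsAsFactors = FALSE)
  if (!is.null(tr$z)) tr$z[tr$z == ""] <- NA_character_
  constraints <- doc$constraints
  if (is.data.frame(constraints))
    constraints <- lapply(seq_len(nrow(constraints)), function(i)
      Filter(Negate(is.null), lapply(constraints, function(col) {
        v <- col[[i]]
        if (length(v) == 1 && is.na(v)) NULL else v
      })))
  sc <- kinetic_scheme(doc$name, as.data.frame(doc$states), tr,
                       constraints = constraints)
  if (!is.null(doc$flags)) attr(sc, "flags") <- doc$flags
  params <- NULL
  if (!is.null(doc$params))
    params <- parameter_set(unlist(doc$params$values), VT = doc$params$VT,
                            e = doc$params$e)
  list(scheme = sc, params = params)
}

# Header block of key: value comment lines.
.write_header <- function(con, fields) {
  for (nm in names(fields))
    writeLines(sprintf("# %s: %s", nm, fields[[nm]]), con)
}

.read_header <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^# ([^:]+): (.*)$", hdr))
  out <- list()
  for (m in kv) if (length(m) == 3) out[[m[2]]] <- m[3]
  out
}

#' Write a trace set as delimited text
#'
#' Tab-separated columns `id`, `Va`, `ta`, `Vd`, `td`, `holding`, `time`,
#' `po`, `sigma`, preceded by a `#`-comment header carrying the condition
#' and generation metadata.
#'
#' @param traceset a `trace_set`.
#' @param path output file.
#' @param meta named list of extra header fields (e.g. seed, config echo).
#' @return `path`, invisibly.
#' @export
write_traceset <- function(traceset, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  .write_header(con, c(list(format = "hcn2kinetics/traceset",
                            condition = traceset$condition), meta))
  rows <- lapply(traceset$traces, function(tr) {
    segs <- tr$protocol$segments
    data.frame(id = tr$id,
               Va = segs$voltage[1], ta = segs$duration[1],
               Vd = if (nrow(segs) > 1) segs$voltage[2] else NA,
               td = if (nrow(segs) > 1) segs$duration[2] else NA,
               holding = tr$protocol$holding,
               time = tr$times, po = tr$po, sigma = tr$sigma)
  })
  utils::write.table(do.call(rbind, rows), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace set written by [write_traceset()]
#'
#' @param path input file.
#' @return a `trace_set` (double-pulse protocols reconstructed from the
#'   per-trace metadata columns).
#' @export
read_traceset <- function(path) {
  hdr <- .read_header(path)
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed trace file '", path, "': ",
                             conditionMessage(e)))
  need <- c("id", "Va", "ta", "Vd", "td", "holding", "time", "po", "sigma")
  if (!all(need %in% names(tab)))
    stop("malformed trace file '", path, "': missing columns ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  traces <- lapply(split(tab, factor(tab$id, levels = unique(tab$id))),
                   function(d) {
    pr <- if (is.na(d$Vd[1]))
      voltage_protocol(data.frame(voltage = d$Va[1], duration = d$ta[1]),
                       holding = d$holding[1], id = d$id[1])
    else double_pulse(d$Va[1], d$ta[1], d$Vd[1], d$td[1],
                      holding = d$holding[1], id = d$id[1])
    list(id = d$id[1], protocol = pr, times = d$time, po = d$po,
         sigma = d$sigma)
  })
  trace_set(unname(traces),
            condition = if (!is.null(hdr$condition)) hdr$condition else "")
}

#' Export a trajectory as delimited text
#'
#' Tab-separated: `time`, `voltage`, one column per state, `po`; protocol
#' metadata in the `#` header.
#'
#' @param traj a `trajectory`.
#' @param path output file.
#' @param meta named list of extra header fields.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  segs <- traj$protocol$segments
  .write_header(con, c(list(
    format = "hcn2kinetics/trajectory",
    scheme = traj$scheme$name,
    holding = traj$protocol$holding,
    segments = paste(sprintf("%g mV/%g s", segs$voltage, segs$duration),
                     collapse = "; ")), meta))
  tab <- data.frame(time = traj$times, voltage = traj$voltage,
                    traj$occupancy, po = open_probability(traj),
                    check.names = FALSE)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a model-ranking table as delimited text
#' @param ranking data.frame from [rank_models()].
#' @param path output file.
#' @param meta named list of extra header fields.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  .write_header(con, c(list(format = "hcn2kinetics/ranking"), meta))
  utils::write.table(ranking, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
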