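## Plain-text I/O: xvg-compatible two-column curves, CSV trajectories,
## flat key:value parameter files, all with provenance headers.

.pkg_version <- function()
  tryCatch(as.character(utils::packageVersion("gleml")),
           error = function(e) "dev")

.provenance_header <- function(extra = character()) {
  c(sprintf("# gleml %s", .pkg_version()),
    sprintf("# date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    extra)
}

#' Read a two-column observable curve
#'
#' Accepts xvg-style files (lines starting with `#` or `@` ignored) and CSV;
#' an optional header row like `t_ps,msd_nm2` declares columns and units.
#' Times must be sorted and all rows numeric.
#'
#' @param path file path.
#' @param kind curve kind if the file does not declare one (default `"msd"`).
#' @return an [observable_curve()].
#' @export
read_curve <- function(path, kind = "msd") {
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*[#@]", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  lineno <- which(keep)
  ## kind may be declared in a comment header
  kd <- grep("^#\\s*kind:", raw, value = TRUE)
  if (length(kd)) kind <- trimws(sub("^#\\s*kind:", "", kd[1]))
  if (!length(lines)) stop("no data rows in ", path)
  sep <- if (grepl(",", lines[1])) "," else NULL
  split1 <- function(x) {
    if (is.null(sep)) strsplit(trimws(x), "\\s+")[[1]]
    else trimws(strsplit(x, ",")[[1]])
  }
  first <- split1(lines[1])
  header <- suppressWarnings(any(is.na(as.numeric(first))))
  if (header) { lines <- lines[-1]; lineno <- lineno[-1] }
  vals <- lapply(lines, function(x) suppressWarnings(as.numeric(split1(x))))
  bad <- which(vapply(vals, function(v) length(v) < 2L || anyNA(v), logical(1)))
  if (length(bad))
    stop("non-numeric or incomplete data at line ", lineno[bad[1]],
         " of ", path)
  t <- vapply(vals, `[[`, numeric(1), 1L)
  v <- vapply(vals, `[[`, numeric(1), 2L)
  if (is.unsorted(t, strictly = TRUE))
    stop("times in ", path, " are not strictly increasing")
  observable_curve(t, v, kind)
}

#' Write an observable curve as two-column text
#'
#' The output carries a provenance header (package version, date, kind,
#' units, and any extra metadata such as the seed) and round-trips through
#' [read_curve()] losslessly at full double precision.
#'
#' @param curve an [observable_curve()].
#' @param path file path.
#' @param extra extra header lines (each will be prefixed with `"# "`).
#' @export
write_curve <- function(curve, path, extra = character()) {
  kind <- attr(curve, "kind")
  units <- attr(curve, "units")
  hdr <- .provenance_header(c(
    sprintf("# kind: %s", kind),
    sprintf("# units: time %s, value %s", units[["time"]], units[["value"]]),
    if (length(extra)) paste("#", extra)))
  body <- sprintf("%.17g %.17g", curve$time, curve$value)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a 2D trajectory from CSV
#'
#' Expects columns `t`, `x`, `y` (ps, nm, nm; a header row is allowed and
#' `#`/`@` comment lines are ignored) with a uniform time step.  The mass may
#' be declared as a header comment `# mass: <g/mol>`.
#'
#' @param path file path.
#' @param mass particle mass (g/mol) if not declared in the file.
#' @return a [trajectory2d()].
#' @export
read_trajectory <- function(path, mass = 1) {
  raw <- readLines(path, warn = FALSE)
  md <- grep("^#\\s*mass:", raw, value = TRUE)
  if (length(md)) mass <- as.numeric(trimws(sub("^#\\s*mass:", "", md[1])))
  keep <- !grepl("^\\s*[#@]", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  sep <- if (grepl(",", lines[1])) "," else "\\s+"
  first <- strsplit(trimws(lines[1]), sep)[[1]]
  if (suppressWarnings(any(is.na(as.numeric(first))))) lines <- lines[-1]
  m <- do.call(rbind, lapply(lines, function(x)
    suppressWarnings(as.numeric(strsplit(trimws(x), sep)[[1]]))))
  if (anyNA(m) || ncol(m) < 3L)
    stop("trajectory file must contain numeric t, x, y columns")
  trajectory2d(m[, 1], m[, 2], m[, 3], mass = mass)
}

#' Write a 2D trajectory as CSV
#'
#' @param traj a [trajectory2d()].
#' @param path file path.
#' @param extra extra header lines.
#' @export
write_trajectory <- function(traj, path, extra = character()) {
  hdr <- .provenance_header(c(
    sprintf("# mass: %g", traj$mass),
    "# units: t ps, x nm, y nm",
    if (length(extra)) paste("#", extra)))
  body <- sprintf("%.17g,%.17g,%.17g", traj$times, traj$pos[, 1], traj$pos[, 2])
  writeLines(c(hdr, "t,x,y", body), path)
  invisible(path)
}

#' Read GLE parameters from a flat key:value file
#'
#' A flat YAML mapping with keys `mass`, `temperature`, `omega_s`, `omega_p`,
#' `tau`, `lam` and optionally `nu`, `delta`, `dim`, `kernel` (units as in
#' [gle_params()]).
#'
#' @param path file path.
#' @return a [gle_params()] object.
#' @export
read_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("mass", "temperature", "omega_s", "omega_p", "tau", "lam")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("parameter file misses keys: ", toString(miss))
  gle_params(mass = cfg$mass, temperature = cfg$temperature,
             omega_s = cfg$omega_s, omega_p = cfg$omega_p, tau = cfg$tau,
             lam = cfg$lam,
             delta = if (is.null(cfg$delta)) 1 else cfg$delta,
             nu = if (is.null(cfg$nu)) cfg$lam *
               (if (is.null(cfg$delta)) 1 else cfg$delta) else cfg$nu,
             dim = if (is.null(cfg$dim)) 2 else cfg$dim,
             kernel = if (is.null(cfg$kernel)) "prabhakar" else cfg$kernel)
}
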