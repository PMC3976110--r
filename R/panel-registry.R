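#' @include AllClasses.R
NULL

#' Convert between Tm summary statistics and detection windows
#'
#' Published marker Tm windows are mean +/- 3SD intervals.
#' `windowFromStats()` builds the closed interval `[mean - 3*sd,
#' mean + 3*sd]`; `sdFromWindow()` inverts the convention, recovering
#' `sd = (high - low) / 6` from a printed range. The two functions
#' round-trip exactly (up to floating point).
#'
#' @param mean mean Tm in degrees C.
#' @param sd standard deviation of the Tm in degrees C; must be >= 0.
#' @param window length-2 numeric `c(low, high)` with `low <= high`.
#' @return `windowFromStats()`: length-2 numeric window;
#'   `sdFromWindow()`: a single numeric SD in degrees C.
#' @examples
#' windowFromStats(81.5, 0.0667)   # IL19 window, ~[81.3, 81.7]
#' sdFromWindow(c(81.3, 81.7))     # 0.0667
#' @export
windowFromStats <- function(mean, sd) {
    stopifnot(is.numeric(mean), length(mean) == 1,
              is.numeric(sd), length(sd) == 1)
    if (is.na(sd) || sd < 0)
        stop("sd must be a non-negative number, got ", sd)
    c(mean - 3 * sd, mean + 3 * sd)
}

#' @rdname windowFromStats
#' @export
sdFromWindow <- function(window) {
    stopifnot(is.numeric(window), length(window) == 2)
    if (window[2] < window[1])
        stop("window must satisfy low <= high")
    (window[2] - window[1]) / 6
}

.builtinPanelNames <- function() {
    dir <- system.file("extdata", "panels", package = "meltID")
    sub("\\.txt$", "", list.files(dir, pattern = "\\.txt$"))
}

#' Built-in body-fluid HRM assay panels
#'
#' Returns one of the published assay panels: six singleplexes
#' (`singleplex_<MARKER>`), three duplexes (`duplex_blood_menstrual`,
#' `duplex_saliva_semen`, `duplex_vaginal_skin`), the epithelial triplex
#' (`triplex_epithelial`; HTN3/IL19/IL1F7), and the all-body-fluids
#' `hexaplex`. Singleplex, duplex and triplex panels use the original
#' primer designs (65-90 degC melt range); the hexaplex uses the
#' redesigned primer set (73-90 degC) and carries the genomic-DNA product
#' window 80.2-80.9 degC originating from the IL19 primers.
#'
#' @param name panel identifier (see above).
#' @return an [HRMPanel].
#' @examples
#' builtinPanel("duplex_blood_menstrual")
#' @export
builtinPanel <- function(name) {
    valid <- .builtinPanelNames()
    if (length(name) != 1 || !name %in% valid)
        stop("unknown panel '", name, "'; valid names: ",
             paste(valid, collapse = ", "))
    readPanelFile(system.file("extdata", "panels", paste0(name, ".txt"),
                              package = "meltID"))
}

#' Read and write panels as plain-text configuration
#'
#' Panels serialize to a key-value text format: a header block
#' (`panel`, `melt_range`, `grid_step`, optional `dna_window`) followed
#' by one block per marker separated by blank lines (`marker`, `fluid`,
#' `tm_mean` with one value per product, one `window: low high` line per
#' product, optional `required_window` 1-based index, `amplicon_size`,
#' `primer_fwd`, `primer_rev`). `writePanelFile()` followed by
#' `readPanelFile()` reproduces the panel.
#'
#' @param path file path.
#' @param panel an [HRMPanel] to serialize.
#' @return `readPanelFile()`: an [HRMPanel]; `writePanelFile()`: `path`,
#'   invisibly.
#' @export
readPanelFile <- function(path) {
    if (!file.exists(path)) stop("panel file not found: ", path)
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[!grepl("^#", lines)]
    ## split into blank-line-separated blocks
    grp <- cumsum(lines == "")
    blocks <- split(lines[lines != ""], grp[lines != ""])
    kv <- function(block) {
        m <- regmatches(block, regexec("^([a-z_]+):\\s*(.*)$", block))
        bad <- vapply(m, length, 1L) != 3L
        if (any(bad)) stop("malformed panel line: ", block[bad][1])
        data.frame(key = vapply(m, `[`, "", 2),
                   value = vapply(m, `[`, "", 3), stringsAsFactors = FALSE)
    }
    num <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
    head_kv <- kv(blocks[[1]])
    getv <- function(df, key, required = TRUE) {
        v <- df$value[df$key == key]
        if (required && !length(v)) stop("panel file missing key: ", key)
        v
    }
    name <- getv(head_kv, "panel")
    melt_range <- num(getv(head_kv, "melt_range"))
    grid_step <- num(getv(head_kv, "grid_step"))
    dnaw <- getv(head_kv, "dna_window", required = FALSE)
    dnaw <- if (length(dnaw)) num(dnaw) else numeric(0)
    rows <- list()
    for (b in blocks[-1]) {
        d <- kv(b)
        means <- num(getv(d, "tm_mean"))
        wins <- lapply(d$value[d$key == "window"], num)
        if (length(wins) != length(means))
            stop("marker ", getv(d, "marker"),
                 ": need one window per tm_mean value")
        req <- getv(d, "required_window", required = FALSE)
        req <- if (length(req)) as.integer(req) else 1L
        size <- getv(d, "amplicon_size", required = FALSE)
        rows[[length(rows) + 1]] <- data.frame(
            marker = getv(d, "marker"),
            fluid = getv(d, "fluid"),
            window_index = seq_along(means),
            tm_mean = means,
            window_low = vapply(wins, `[`, 0, 1),
            window_high = vapply(wins, `[`, 0, 2),
            required = seq_along(means) == req,
            amplicon_size = if (length(size)) as.integer(size) else NA_integer_,
            primer_fwd = c(getv(d, "primer_fwd", required = FALSE), NA)[1],
            primer_rev = c(getv(d, "primer_rev", required = FALSE), NA)[1],
            stringsAsFactors = FALSE)
    }
    new("HRMPanel", name = name, markers = do.call(rbind, rows),
        meltRange = melt_range, gridStep = grid_step, dnaWindow = dnaw)
}

#' @rdname readPanelFile
#' @export
writePanelFile <- function(panel, path) {
    stopifnot(is(panel, "HRMPanel"))
    fmt <- function(x) format(x, digits = 10, trim = TRUE, scientific = FALSE)
    out <- c(paste0("panel: ", panel@name),
             paste("melt_range:", fmt(panel@meltRange[1]), fmt(panel@meltRange[2])),
             paste("grid_step:", fmt(panel@gridStep)))
    if (length(panel@dnaWindow))
        out <- c(out, paste("dna_window:", fmt(panel@dnaWindow[1]),
                            fmt(panel@dnaWindow[2])))
    m <- panel@markers
    for (mk in unique(m$marker)) {
        w <- m[m$marker == mk, , drop = FALSE]
        w <- w[order(w$window_index), , drop = FALSE]
        out <- c(out, "",
                 paste0("marker: ", mk),
                 paste0("fluid: ", w$fluid[1]),
                 paste("tm_mean:", paste(fmt(w$tm_mean), collapse = " ")),
                 vapply(seq_len(nrow(w)), function(i)
                     paste("window:", fmt(w$window_low[i]), fmt(w$window_high[i])), ""),
                 paste0("required_window: ", which(w$required)))
        if (!is.na(w$amplicon_size[1]))
            out <- c(out, paste0("amplicon_size: ", w$amplicon_size[1]))
        if (!is.na(w$primer_fwd[1]))
            out <- c(out, paste0("primer_fwd: ", w$primer_fwd[1]))
        if (!is.na(w$primer_rev[1]))
            out <- c(out, paste0("primer_rev: ", w$primer_rev[1]))
    }
    writeLines(out, path)
    invisible(path)
}
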