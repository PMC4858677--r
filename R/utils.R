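#' @importFrom S4Vectors metadata "metadata<-"
NULL

pkgVersionString <- function()
    as.character(utils::packageVersion("popExpVar"))

# small fingerprint of an R object (config provenance in output headers);
# machine-local fields (paths) are excluded so reruns of the same analysis
# fingerprint identically
configHash <- function(x) {
    if (inherits(x, "PipelineConfig"))
        x <- unclass(x)[setdiff(names(x), c("outputDir", "input"))]
    bytes <- utf8ToInt(paste(deparse(x), collapse = " "))
    h <- 0
    for (b in bytes) h <- (h * 31 + b) %% 2147483647
    sprintf("%x", h)
}

# every stage derives its own stream from the single top-level seed
deriveSeed <- function(seed, k)
    as.integer((as.double(seed) + 104729 * as.double(k)) %% 2147483647L)

#' Write / read a tab-separated table with a provenance header
#'
#' All result tables the pipeline emits are plain TSV (UTF-8, `.` decimal,
#' no quoting) preceded by one `#` comment line carrying the tool version
#' and a fingerprint of the configuration that produced them.
#'
#' @param df data.frame to write.
#' @param path file path.
#' @param what short label of the table's content.
#' @param config object whose fingerprint goes into the header (optional).
#' @return `writeTsv`: `path`, invisibly. `readTsv`: a data.frame
#'   (comment lines skipped).
#' @export
writeTsv <- function(df, path, what = "table", config = NULL) {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(sprintf("# popExpVar %s %s config=%s", pkgVersionString(),
                       what, configHash(config)), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                      check.names = FALSE)
}
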