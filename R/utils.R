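## condition helpers: bt_config_error = bad options/arguments,
## bt_data_error = inputs that fail a contract.
btStop <- function(class, fmt, ...) {
    msg <- sprintf(fmt, ...)
    stop(structure(
        class = c(class, "bt_error", "error", "condition"),
        list(message = msg, call = sys.call(-1))
    ))
}

btConfigError <- function(fmt, ...) btStop("bt_config_error", fmt, ...)
btDataError <- function(fmt, ...) btStop("bt_data_error", fmt, ...)

.asCompMatrix <- function(x) {
    if (is(x, "CompositionTable")) return(x@values)
    if (is.numeric(x) && is.null(dim(x))) {
        m <- matrix(x, nrow = 1,
                    dimnames = list("S1", names(x) %||%
                                        paste0("F", seq_along(x))))
        return(m)
    }
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- paste0("F", seq_len(ncol(m)))
    m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.fmtIds <- function(x, max = 10) {
    if (length(x) > max)
        x <- c(x[seq_len(max)], sprintf("... (%d more)", length(x) - max))
    paste(x, collapse = ", ")
}
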