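# Minimal s-expression reader for the domain-file dialect.
#
# Tokens are `(`, `)`, double-quoted strings and bare atoms; `;` starts a
# comment running to the end of the line.  Every token carries its line and
# column so that syntax errors can point at the offending place.

sexp_tokenize <- function(text) {
  chars <- strsplit(paste(text, collapse = "\n"), "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- vector("list", 256L)
  nt <- 0L
  push <- function(value, type, line, col) {
    nt <<- nt + 1L
    if (nt > length(toks)) toks[[2L * nt]] <<- NULL
    toks[[nt]] <<- list(value = value, type = type, line = line, col = col)
  }
  i <- 1L; line <- 1L; col <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "\n") { line <- line + 1L; col <- 1L; i <- i + 1L; next }
    if (ch %in% c(" ", "\t", "\r")) { col <- col + 1L; i <- i + 1L; next }
    if (ch == ";") {
      while (i <= n && chars[i] != "\n") i <- i + 1L
      next
    }
    if (ch == "(" || ch == ")") {
      push(ch, if (ch == "(") "open" else "close", line, col)
      i <- i + 1L; col <- col + 1L; next
    }
    if (ch == "\"") {
      j <- i + 1L
      while (j <= n && chars[j] != "\"") {
        if (chars[j] == "\n")
          stop(sprintf("syntax error at line %d, column %d: unterminated string",
                       line, col), call. = FALSE)
        j <- j + 1L
      }
      if (j > n)
        stop(sprintf("syntax error at line %d, column %d: unterminated string",
                     line, col), call. = FALSE)
      push(paste(chars[(i + 1L):(j - 1L)][seq_len(max(0L, j - i - 1L))],
                 collapse = ""),
           "string", line, col)
      col <- col + (j - i + 1L); i <- j + 1L; next
    }
    j <- i
    while (j <= n && !(chars[j] %in% c(" ", "\t", "\r", "\n", "(", ")", ";", "\"")))
      j <- j + 1L
    push(paste(chars[i:(j - 1L)], collapse = ""), "atom", line, col)
    col <- col + (j - i); i <- j
  }
  toks[seq_len(nt)]
}

# Parse tokens into nested lists.  Atoms come back as plain character
# scalars, quoted strings as character with class "sexp_string"; lists carry
# the position of their opening paren in attributes.
sexp_parse <- function(text) {
  toks <- sexp_tokenize(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  read_form <- function() {
    tk <- peek()
    if (is.null(tk)) stop("syntax error: unexpected end of input", call. = FALSE)
    pos <<- pos + 1L
    if (tk$type == "open") {
      items <- list()
      repeat {
        nx <- peek()
        if (is.null(nx))
          stop(sprintf("syntax error at line %d, column %d: unclosed '('",
                       tk$line, tk$col), call. = FALSE)
        if (nx$type == "close") { pos <<- pos + 1L; break }
        items[[length(items) + 1L]] <- read_form()
      }
      attr(items, "line") <- tk$line
      attr(items, "col") <- tk$col
      return(items)
    }
    if (tk$type == "close")
      stop(sprintf("syntax error at line %d, column %d: unexpected ')'",
                   tk$line, tk$col), call. = FALSE)
    out <- tk$value
    if (tk$type == "string") class(out) <- "sexp_string"
    attr(out, "line") <- tk$line
    attr(out, "col") <- tk$col
    out
  }
  forms <- list()
  while (!is.null(peek())) forms[[length(forms) + 1L]] <- read_form()
  forms
}

sexp_is_atom <- function(x) is.character(x) && !inherits(x, "sexp_string")
sexp_atom <- function(x) if (is.character(x)) as.vector(x) else NULL

sexp_where <- function(x) {
  ln <- attr(x, "line"); cl <- attr(x, "col")
  if (is.null(ln)) "" else sprintf(" (line %d, column %d)", ln, cl)
}
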