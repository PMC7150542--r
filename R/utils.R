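# Locale-independent ordering helpers. All token orderings in the package
# (read ids, cluster ids, k-mers) use C byte order so that results are
# identical regardless of the session's collation locale; base sort()/order()
# on character vectors would follow LC_COLLATE and silently change label
# propagation tie-breaks and node numbering between environments.

sort_c <- function(x, decreasing = FALSE) {
  sort(x, decreasing = decreasing, method = "radix")
}

order_c <- function(...) order(..., method = "radix")

min_c <- function(x) sort(x, method = "radix")[1L]
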