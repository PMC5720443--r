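# independent arbitrary-precision oracle for the survival-averaged BED
# formulas, evaluated by direct summation at 50 decimal digits (mpmath via
# the system python), with no log-sum-exp shift: the extended exponent range
# of mpf makes the naive sum exact where doubles underflow.

.oracle_py <- '
import json, sys
import mpmath as mp
mp.mp.dps = 50

def neg_log_wsum(v, ls):
    s = mp.mpf(0)
    for vi, li in zip(v, ls):
        s += mp.mpf(vi) * mp.e**mp.mpf(li)
    return -mp.log(s)

def kernel(v, d, n, alpha, ab):
    ls = [-mp.mpf(alpha) * n * mp.mpf(di) * (1 + mp.mpf(di) / mp.mpf(ab)) for di in d]
    return neg_log_wsum(v, ls)

task = json.load(open(sys.argv[1]))
out = []
for t in task:
    kind = t["kind"]
    if kind == "neg_log_wsum":
        r = neg_log_wsum(t["v"], t["ls"])
    elif kind == "bed_cc":
        r = kernel(t["v"], t["d"], t["n"], t["alpha"], t["ab"]) / mp.mpf(t["alpha"]) - mp.mpf(t["repop"])
    elif kind == "bed_fivc":
        r = kernel(t["v"], t["d"], 1, t["alpha"], t["ab"]) / mp.mpf(t["alpha"]) - mp.mpf(t["repop"]) / t["n"]
    elif kind == "bed_conv":
        d = mp.mpf(t["d"]); r = t["n"] * d * (1 + d / mp.mpf(t["ab"])) - mp.mpf(t["repop"])
    else:
        raise ValueError(kind)
    out.append(mp.nstr(r, 25))
json.dump(out, open(sys.argv[2], "w"))
'

# tasks: list of lists with fields kind/v/d/ls/n/alpha/ab/repop
oracle_eval <- function(tasks) {
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)))
  jsonlite::write_json(tasks, fin, auto_unbox = TRUE, digits = NA)
  py <- tempfile(fileext = ".py")
  on.exit(unlink(py), add = TRUE)
  writeLines(.oracle_py, py)
  status <- system2("python", c(py, fin, fout), stdout = TRUE, stderr = TRUE)
  if (!file.exists(fout))
    stop("oracle run failed: ", paste(status, collapse = "\n"))
  as.numeric(unlist(jsonlite::read_json(fout)))
}

oracle_neg_log_wsum <- function(v, ls)
  oracle_eval(list(list(kind = "neg_log_wsum", v = v, ls = ls)))

oracle_bed_cc <- function(v, d, n, alpha, ab, repop = 0)
  oracle_eval(list(list(kind = "bed_cc", v = v, d = d, n = n,
                        alpha = alpha, ab = ab, repop = repop)))

oracle_bed_fivc <- function(v, d, n, alpha, ab, repop = 0)
  oracle_eval(list(list(kind = "bed_fivc", v = v, d = d, n = n,
                        alpha = alpha, ab = ab, repop = repop)))

# oracle views of package objects
oracle_bed_of_ddvh <- function(kind, x, scheme, params) {
  keep <- x$bins$volume > 0
  d <- (x$bins$lower[keep] + x$bins$upper[keep]) / 2
  v <- x$bins$volume[keep] / 100
  repop <- if (params$includes_repopulation)
    log(2) * scheme$elapsed_time / (params$alpha * params$teff) else 0
  if (kind == "cc")
    oracle_bed_cc(v, d, scheme$n_fractions, params$alpha, params$alpha_beta, repop)
  else
    oracle_bed_fivc(v, d, scheme$n_fractions, params$alpha, params$alpha_beta, repop)
}
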