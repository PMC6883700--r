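#!/usr/bin/env python
"""External CAS cross-check: reduced lex Groebner basis via sympy.

Input JSON: {"nvars": n, "polys": [{"exps": [[...]], "coefs": ["...", ...]}]}
with variable 0 ranked highest.  Output JSON: list of basis polynomials in
the same format, monic, terms in descending lex order.
"""
import json
import sys

import sympy as sp
from sympy import Rational


def main(infile, outfile):
    with open(infile) as fh:
        payload = json.load(fh)
    nv = payload["nvars"]
    xs = sp.symbols(f"v0:{nv}")

    def to_expr(p):
        exps = p["exps"]
        coefs = p["coefs"]
        if isinstance(coefs, str):
            coefs = [coefs]
        if exps and isinstance(exps[0], int):
            exps = [exps]
        if not exps:
            exps = []
        e = sp.Integer(0)
        for row, c in zip(exps, coefs):
            t = Rational(c)
            for v, k in zip(xs, row):
                t *= v ** int(k)
            e += t
        return e

    F = [to_expr(p) for p in payload["polys"]]
    G = sp.groebner(F, *xs, order="lex")
    out = []
    for g in G.exprs:
        poly = sp.Poly(g, *xs).monic()
        exps, coefs = [], []
        for mono, c in poly.terms():
            exps.append([int(k) for k in mono])
            coefs.append(str(Rational(c)))
        out.append({"exps": exps, "coefs": coefs})
    with open(outfile, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
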