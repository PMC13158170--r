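"""Exact LP oracle: solves min c'x s.t. A x <= b, l <= x <= u with HiGHS.

Interchange with R is a JSON metadata file plus raw little-endian
float64 arrays (column-major A), one batch of K bound columns per call.
Output per instance: [status, objective, x (n), marginals of the
inequality rows (m)].
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog

INF = 1e299


def main(prefix: str) -> None:
    with open(prefix + "_meta.json") as fh:
        meta = json.load(fh)
    m, n, k = meta["m"], meta["n"], meta["K"]
    buf = np.fromfile(prefix + "_in.bin", dtype="<f8")
    expected = n + m * n + m * k + n + n * k
    assert buf.size == expected, f"payload size {buf.size} != {expected}"
    pos = 0

    def take(cnt):
        nonlocal pos
        out = buf[pos:pos + cnt]
        pos += cnt
        return out

    c = take(n)
    a = take(m * n).reshape((m, n), order="F")
    b = take(m * k).reshape((m, k), order="F")
    lo = take(n)
    up = take(n * k).reshape((n, k), order="F")
    lo = np.where(lo <= -INF, -np.inf, lo)
    up = np.where(up >= INF, np.inf, up)

    out = []
    for j in range(k):
        res = linprog(c, A_ub=a, b_ub=b[:, j],
                      bounds=np.column_stack([lo, up[:, j]]),
                      method="highs")
        if res.status == 0:
            out.append(np.concatenate([[0.0], [res.fun], res.x,
                                       res.ineqlin.marginals]))
        else:
            out.append(np.concatenate([[float(res.status)], [np.nan],
                                       np.full(n, np.nan),
                                       np.full(m, np.nan)]))
    np.concatenate(out).astype("<f8").tofile(prefix + "_out.bin")


if __name__ == "__main__":
    main(sys.argv[1])
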