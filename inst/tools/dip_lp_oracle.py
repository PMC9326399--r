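"""Independent dip-statistic oracle.

Solves, for each input sample, the definition of the dip directly: the
nearest unimodal CDF in sup norm. The fitted CDF is piecewise linear with
knots at the distinct data values and may carry a single atom at its mode;
for every candidate mode location (at a value, or inside a gap) the minimal
band half-width eps is found by linear programming (HiGHS), and the dip is
the minimum over candidates, floored at 1/(2n).

stdin: JSON list of numeric lists. stdout: JSON list of dips.
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog


def dip_lp(v):
    xs = np.sort(np.asarray(v, dtype=float))
    n = xs.size
    x, cnt = np.unique(xs, return_counts=True)
    m = x.size
    if m == 1:
        return 1.0 / (2 * n)
    Fr = np.cumsum(cnt) / n
    Fl = (np.cumsum(cnt) - cnt) / n

    def solve_one(mode_node=None, gap_after=None):
        has_h = mode_node is not None
        nv = m + (1 if has_h else 0) + 1
        ei = nv - 1
        hidx = m if has_h else None
        A, b = [], []

        def add(row, rhs):
            A.append(row)
            b.append(rhs)

        for j in range(m):
            r = np.zeros(nv); r[j] = -1; r[ei] = -1; add(r, -Fr[j])
            r = np.zeros(nv); r[j] = 1; r[ei] = -1; add(r, Fr[j])
            if not has_h or j != mode_node:
                r = np.zeros(nv); r[j] = 1; r[ei] = -1; add(r, Fl[j])
                r = np.zeros(nv); r[j] = -1; r[ei] = -1; add(r, -Fl[j])
            if j < m - 1:
                r = np.zeros(nv); r[j] = 1; r[j + 1] = -1; add(r, 0.0)
        if has_h:
            j = mode_node
            r = np.zeros(nv); r[hidx] = 1; r[ei] = -1; add(r, Fl[j])
            r = np.zeros(nv); r[hidx] = -1; r[ei] = -1; add(r, -Fl[j])
            r = np.zeros(nv); r[hidx] = 1; r[j] = -1; add(r, 0.0)
            if j > 0:
                r = np.zeros(nv); r[j - 1] = 1; r[hidx] = -1; add(r, 0.0)
            lx = np.concatenate([x[:j], [x[j]]])
            lv = list(range(j)) + [hidx]
            rx = x[j:]
            rv = list(range(j, m))
        else:
            lx = x[: gap_after + 1]
            lv = list(range(gap_after + 1))
            rx = x[gap_after + 1:]
            rv = list(range(gap_after + 1, m))

        def shape(px, pv, convex):
            for i in range(len(px) - 2):
                d1 = px[i + 1] - px[i]
                d2 = px[i + 2] - px[i + 1]
                r = np.zeros(nv)
                r[pv[i]] = 1.0 / d1
                r[pv[i + 1]] = -1.0 / d1 - 1.0 / d2
                r[pv[i + 2]] = 1.0 / d2
                # r @ g = weighted second difference (>= 0 iff convex)
                add(-r if convex else r, 0.0)

        shape(lx, lv, convex=True)
        shape(rx, rv, convex=False)
        c = np.zeros(nv)
        c[ei] = 1.0
        bounds = [(0.0, 1.0)] * (nv - 1) + [(0.0, 1.0)]
        res = linprog(c, A_ub=np.array(A), b_ub=np.array(b), bounds=bounds,
                      method="highs")
        return res.fun if res.status == 0 else np.inf

    best = np.inf
    for j in range(m):
        best = min(best, solve_one(mode_node=j))
    for j in range(m - 1):
        best = min(best, solve_one(gap_after=j))
    return max(best, 1.0 / (2 * n))


def main():
    cases = json.load(sys.stdin)
    json.dump([dip_lp(v) for v in cases], sys.stdout)


if __name__ == "__main__":
    main()
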