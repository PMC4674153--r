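"""Dev-only ground truth for the dip statistic.

D(sample) = min over unimodal CDFs G of sup_x |F_n(x) - G(x)|, where G is
convex on (-inf, m], concave on [m, inf), continuous except possibly a jump
at the mode m.  Piecewise-linear G with knots at the distinct data points
suffices; for each mode placement the min-sup problem is a small LP.

Convention: result floored at 1/(2n) (only binds for constant samples).
"""
import sys, json
import numpy as np
from scipy.optimize import linprog


def dip_lp(x):
    x = np.asarray(x, float)
    n = len(x)
    t, cnt = np.unique(x, return_counts=True)
    K = len(t)
    u = np.cumsum(cnt) / n          # F_n(t_k)
    l = np.concatenate([[0.0], u[:-1]])  # left limits
    if K == 1:
        return 0.5 / n
    best = np.inf

    def solve(c, A_ub, b_ub):
        res = linprog(c, A_ub=A_ub, b_ub=b_ub, bounds=[(None, None)] * len(c),
                      method="highs")
        return res.fun if res.status == 0 else np.inf

    # ---- case A_k: mode in gap (t_k, t_{k+1}), k = 0..K (0: all concave,
    # K: all convex).  Vars: g_1..g_K, eps.
    for k in range(K + 1):
        rows, rhs = [], []
        E = K  # eps index
        def row():
            r = np.zeros(K + 1)
            rows.append(r)
            return r
        for i in range(K):
            r = row(); r[i] = -1; r[E] = -1; rhs.append(-u[i])   # g_i >= u_i-eps
            r = row(); r[i] = 1;  r[E] = -1; rhs.append(l[i])    # g_i <= l_i+eps
            r = row(); r[i] = -1; rhs.append(0.0)                # g_i >= 0
            r = row(); r[i] = 1;  rhs.append(1.0)                # g_i <= 1
        for i in range(K - 1):
            r = row(); r[i] = 1; r[i + 1] = -1; rhs.append(0.0)  # monotone
        # convex on 1..k (python idx 0..k-1), consecutive triples
        for i in range(1, k - 1):
            d1, d2 = t[i] - t[i - 1], t[i + 1] - t[i]
            r = row()
            r[i - 1] = -d2; r[i] = d1 + d2; r[i + 1] = -d1
            rhs.append(0.0)
        # concave on k+1..K (python idx k..K-1)
        for i in range(k + 1, K - 1):
            d1, d2 = t[i] - t[i - 1], t[i + 1] - t[i]
            r = row()
            r[i - 1] = d2; r[i] = -(d1 + d2); r[i + 1] = d1
            rhs.append(0.0)
        c = np.zeros(K + 1); c[E] = 1
        best = min(best, solve(c, np.array(rows), np.array(rhs)))

    # ---- case B_j: mode at t_j with jump.  Vars: g_1..g_K (g_j plays the
    # role of a=G(t_j^-)), b, eps.
    for j in range(K):
        rows, rhs = [], []
        B, E = K, K + 1
        def row():
            r = np.zeros(K + 2)
            rows.append(r)
            return r
        for i in range(K):
            if i == j:
                r = row(); r[i] = -1; r[E] = -1; rhs.append(-l[i])  # a >= l_j-eps
                r = row(); r[i] = 1;  r[E] = -1; rhs.append(l[i])   # a <= l_j+eps
            else:
                r = row(); r[i] = -1; r[E] = -1; rhs.append(-u[i])
                r = row(); r[i] = 1;  r[E] = -1; rhs.append(l[i])
            r = row(); r[i] = -1; rhs.append(0.0)
            r = row(); r[i] = 1;  rhs.append(1.0)
        r = row(); r[B] = -1; r[E] = -1; rhs.append(-u[j])           # b >= u_j-eps
        r = row(); r[B] = 1;  r[E] = -1; rhs.append(u[j])            # b <= u_j+eps
        r = row(); r[B] = 1; rhs.append(1.0)
        r = row(); r[j] = 1; r[B] = -1; rhs.append(0.0)              # a <= b
        for i in range(K - 1):  # monotone g, with b standing in above t_j
            r = row()
            if i == j:
                r[B] = 1
            else:
                r[i] = 1
            r[i + 1] = -1
            rhs.append(0.0)
        # convex on points 1..j (values g_1..g_{j-1}, a)
        for i in range(1, j):
            d1, d2 = t[i] - t[i - 1], t[i + 1] - t[i]
            r = row()
            r[i - 1] = -d2; r[i] = d1 + d2; r[i + 1] = -d1
            rhs.append(0.0)
        # concave on points j..K (values b, g_{j+1}..g_K)
        for i in range(j + 1, K - 1):
            d1, d2 = t[i] - t[i - 1], t[i + 1] - t[i]
            r = row()
            r[i - 1 if i - 1 != j else B] = d2
            r[i] = -(d1 + d2); r[i + 1] = d1
            rhs.append(0.0)
        c = np.zeros(K + 2); c[E] = 1
        best = min(best, solve(c, np.array(rows), np.array(rhs)))

    return max(best, 0.5 / n)


if __name__ == "__main__":
    samples = json.load(sys.stdin)
    print(json.dumps([dip_lp(s) for s in samples]))
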