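>REF
EHACMQVWALQLHKRFKQFFCLNRAYDGLLGRYYNGINGHWLGQCPVQGAWWIGNGIHMT
>focal_nonC4
EHACMQVWALQLHKRFKQFFCLNRAYDGLLGRYYNGINGHWLGQCPVQGAWWIGNGIHMT
>nonC4_1
EHACMQVWALQLPKRFKQFFCLNRAYDGLLGRYYNGINGHWLGQCVVKGAWWIGNGHHMT
>nonC4_2
EHACMQVWALQLHKRFKQFFCLNRAYDGLLGRYYNGINGHWLGQCPVQGAWWIGNGIHMT
>nonC4_3
EHACMQVWALQLHKRFKQFFCLNRAYDGLLGRYYNGINGHWLGQCPVQGAWWIGNGIHMT
>weak_1
EHACMQVWALQLHKRFKQFFCLNRAYDGLLGRYYNGINGHWLGQCPVQGAWWIGNGIHMT
>weak_2
EHACMQVWALQLHKRFKQFFCLNRAYDGLLGRYYNGINGHWLGQCPVQGAWWIGNGIHMT
>focal_C4
EHACMQVWALQLPKRFKQFFCLTRCYDGLLGRYYNQINGGWLGQCVVKGAWWIGNGHHMT
>C4_1
---CMQVWALQLPKRFKQFFCLNRCYDGLLGRYYNQINGGWLGQCVVKGAWWIGNGHHMT
>C4_2
EHACMQVWALQLPKRFKQFFCLTRCYDGLLGRYYNGINGGWLGQCVVKGAWWIGNGHHMT
>C4_3
EHACMQVWALQLPKRFKQFFCLTRCYDGLLGRYYNQINGHWLGQCVVKGAWWIGNGHHMT
>C4_4
EHACMQVWALQLPKRFKQFFCLTRCYDGLLGRYYNQINGGWLGQCVVKGAWWIGNGHHMT
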