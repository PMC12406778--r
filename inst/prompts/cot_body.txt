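Here is a list of possible labels separated by semicolons:
{category_list}

{examples}Response: "{response}"

Reason step by step about which label fits this response best. Finish your reply with the marker "ANSWER:" followed by the number of the chosen label.
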