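Responses have been pre-screened and should all fit under one cohesive theme.

Here are the example responses, separated by semicolons: {examples}

Here is a list of possible labels separated by semicolons:
{category_list}
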