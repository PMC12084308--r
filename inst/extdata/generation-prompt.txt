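Task:
You will be provided with an input word: write the first 3 words you associate to it separated by a comma
No additional output text is allowed

Constraints:
No carriage return characters are allowed in the answers
Answers should be as short as possible

Example:
Input: sea
Output: water, beach, sun
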